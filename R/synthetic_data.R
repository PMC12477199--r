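#' Configuration for the synthetic volatilomics generator
#'
#' The defaults emulate the structure of a long-term cigar-aging study:
#' six sampling time points (S0..S5) with six biological replicates
#' each, pooled QC injections, four aging stages G1 (S0-S1), G2 (S2),
#' G3 (S3), G4 (S4-S5), a compound-class mix dominated by terpenoids,
#' esters, heterocyclics and ketones, planted monotone-up,
#' monotone-down, transient and flat trajectories with multiplicative
#' log-normal noise, odor thresholds spanning several orders of
#' magnitude, and one pathway enriched among up-trending compounds.
#'
#' @param n_compounds number of volatile compounds (>= 10).
#' @param class_mix named proportions over compound classes; must sum to 1.
#' @param n_timepoints number of sampling time points (default 6).
#' @param replicates_per_timepoint biological replicates per time point
#'   (default 6).
#' @param n_qc number of pooled QC samples (default 4).
#' @param trend_mix named proportions over `up`, `down`, `transient`,
#'   `flat`; must sum to 1.
#' @param effect_log2fc planted log2 fold change of stage-mean abundance
#'   between G4 and G1 for trending compounds (default 2).
#' @param noise_cv multiplicative log-normal coefficient of variation of
#'   biological replicates (default 0.2).
#' @param qc_cv coefficient of variation of pooled QC injections
#'   (default 0.05); must be below `noise_cv` so QCs cluster tighter.
#' @param base_log10_range log10 range of per-compound base
#'   concentrations (ug/g); default `c(-3, 0)` puts typical compounds at
#'   nanogram-to-microgram-per-gram levels.
#' @param threshold_log10_range log10 range of odor thresholds (ug/g).
#' @param n_pathways number of pathways in the compound-to-pathway map.
#' @param enriched_pathway_fraction_up fraction of up-trending compounds
#'   planted into the enriched pathway (default 0.5).
#' @param n_key_up,n_key_down number of planted key aroma compounds
#'   among up- and down-trending compounds (defaults 14 and 7).
#' @param is_cv coefficient of variation of the simulated
#'   internal-standard peak areas (default 0.02).
#' @param seed integer RNG seed; identical configs generate identical
#'   datasets.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_compounds = 200,
                         class_mix = c(terpenoids = 0.21, esters = 0.18,
                                       heterocyclics = 0.12, ketones = 0.10,
                                       aldehydes = 0.09, others = 0.30),
                         n_timepoints = 6,
                         replicates_per_timepoint = 6,
                         n_qc = 4,
                         trend_mix = c(up = 0.15, down = 0.10,
                                       transient = 0.15, flat = 0.60),
                         effect_log2fc = 2,
                         noise_cv = 0.2,
                         qc_cv = 0.05,
                         base_log10_range = c(-3, 0),
                         threshold_log10_range = c(-3, 1),
                         n_pathways = 15,
                         enriched_pathway_fraction_up = 0.5,
                         n_key_up = 14,
                         n_key_down = 7,
                         is_cv = 0.02,
                         seed = 17) {
  if (n_compounds < 10) stop("n_compounds must be >= 10", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix proportions must sum to 1", call. = FALSE)
  if (abs(sum(trend_mix) - 1) > 1e-9)
    stop("trend_mix proportions must sum to 1", call. = FALSE)
  need <- c("up", "down", "transient", "flat")
  if (!all(need %in% names(trend_mix)))
    stop("trend_mix needs proportions for up, down, transient, flat",
         call. = FALSE)
  if (trend_mix[["up"]] == 0 && enriched_pathway_fraction_up > 0)
    stop("cannot plant an enriched pathway among up-trending compounds ",
         "when trend_mix['up'] is 0", call. = FALSE)
  if (effect_log2fc <= 0 || noise_cv <= 0)
    stop("effect_log2fc and noise_cv must be positive", call. = FALSE)
  structure(
    list(n_compounds = n_compounds, class_mix = class_mix,
         n_timepoints = n_timepoints,
         replicates_per_timepoint = replicates_per_timepoint, n_qc = n_qc,
         trend_mix = trend_mix, effect_log2fc = effect_log2fc,
         noise_cv = noise_cv, qc_cv = qc_cv,
         base_log10_range = base_log10_range,
         threshold_log10_range = threshold_log10_range,
         n_pathways = n_pathways,
         enriched_pathway_fraction_up = enriched_pathway_fraction_up,
         n_key_up = n_key_up, n_key_down = n_key_down, is_cv = is_cv,
         seed = seed),
    class = "synth_config")
}

#' Strong-separation benchmark configuration
#'
#' The model-quality benchmark dataset: two stages far apart in volatile
#' space, as in a long aging contrast where a large share of the profile
#' is remodelled. Compared with [synth_config()] defaults it plants a
#' 16-fold stage-extreme change (`effect_log2fc = 4`) in half of the
#' compounds (30% up, 20% down), with tighter replicate noise
#' (`noise_cv = 0.1`). With only a few hundred compounds, a high
#' informative fraction is what keeps cross-validated predictions from
#' being dominated by the weight noise of uninformative columns, so this
#' preset measures separation strength rather than a small-panel noise
#' floor.
#'
#' @param ... overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_strong <- function(...) {
  args <- list(effect_log2fc = 4, noise_cv = 0.1,
               trend_mix = c(up = 0.3, down = 0.2,
                             transient = 0.1, flat = 0.4))
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

# Largest-remainder allocation of n items to proportions p (sums to n).
allocate_counts <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# Map n_timepoints to the four aging stages; 6 points reproduce the
# study layout G1(S0,S1) G2(S2) G3(S3) G4(S4,S5).
stage_of_timepoint <- function(n_timepoints) {
  if (n_timepoints < 4) stop("need at least 4 time points", call. = FALSE)
  as.integer(cut(seq_len(n_timepoints), 4))
}

# Per-stage abundance multipliers for one compound trend.
trend_multipliers <- function(trend, effect_log2fc) {
  g <- 0:3
  switch(trend,
         up        = 2^(effect_log2fc * g / 3),
         down      = 2^(-effect_log2fc * g / 3),
         transient = c(1, 2^effect_log2fc, 1, 1),
         flat      = rep(1, 4),
         stop("unknown trend: ", trend, call. = FALSE))
}

#' Generate a synthetic volatilomics dataset with known ground truth
#'
#' Simulates true concentrations as
#' `base * stage_multiplier * exp(N(0, sigma))` with
#' `sigma = sqrt(log(1 + noise_cv^2))` (strictly positive, CV-
#' parameterised, the standard model for MS intensities), converts them
#' to peak areas through a simulated internal standard (per-sample areas
#' with `is_cv` noise), and emits pooled QC samples as the per-compound
#' mean across biological samples with `qc_cv` noise. Up/down trends are
#' geometric across the four stages so that the expected stage-mean
#' log2(G4/G1) equals `effect_log2fc`; transient compounds peak at G2.
#'
#' @param cfg a [synth_config()].
#' @return A list of class `synth_dataset`: `ft` (peak-area
#'   [feature_table()]), `ann` ([annotation_table()]), `design`
#'   ([stage_design()]), `isp` ([internal_standard_params()]), and
#'   `truth` (a list with `trend` per compound, `base` abundances,
#'   `enriched_pathway`, `key_up`, `key_down`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)

  n <- cfg$n_compounds
  compound_ids <- sprintf("VC%04d", seq_len(n))

  ## trends: exact counts, shuffled
  trend_counts <- allocate_counts(n, cfg$trend_mix[c("up", "down",
                                                     "transient", "flat")])
  trend <- sample(rep(names(trend_counts), trend_counts))
  names(trend) <- compound_ids

  ## classes: exact counts, shuffled
  class_counts <- allocate_counts(n, cfg$class_mix)
  compound_class <- sample(rep(names(class_counts), class_counts))

  ## design
  tp_stage <- stage_of_timepoint(cfg$n_timepoints)
  tp_labels <- sprintf("S%d", seq_len(cfg$n_timepoints) - 1L)
  bio_tp <- rep(seq_len(cfg$n_timepoints), each = cfg$replicates_per_timepoint)
  bio_rep <- rep(seq_len(cfg$replicates_per_timepoint), cfg$n_timepoints)
  bio_ids <- sprintf("%s_R%d", tp_labels[bio_tp], bio_rep)
  qc_ids <- if (cfg$n_qc > 0) sprintf("QC_%d", seq_len(cfg$n_qc)) else character(0)
  design <- stage_design(
    sample_id = c(bio_ids, qc_ids),
    time_point = c(tp_labels[bio_tp], rep("QC", cfg$n_qc)),
    stage = c(sprintf("G%d", tp_stage[bio_tp]), rep("QC", cfg$n_qc)),
    replicate_index = c(bio_rep, seq_len(cfg$n_qc)))

  ## true concentrations
  base <- 10^stats::runif(n, cfg$base_log10_range[1], cfg$base_log10_range[2])
  names(base) <- compound_ids
  mult <- t(vapply(trend, trend_multipliers, numeric(4),
                   effect_log2fc = cfg$effect_log2fc))
  sigma <- sqrt(log(1 + cfg$noise_cv^2))
  n_bio <- length(bio_ids)
  conc <- base * mult[, tp_stage[bio_tp], drop = FALSE] *
    matrix(exp(stats::rnorm(n * n_bio, 0, sigma)), n, n_bio)
  colnames(conc) <- bio_ids

  ## pooled QC: per-compound mean across biological samples + small noise
  if (cfg$n_qc > 0) {
    sigma_qc <- sqrt(log(1 + cfg$qc_cv^2))
    qc <- rowMeans(conc) *
      matrix(exp(stats::rnorm(n * cfg$n_qc, 0, sigma_qc)), n, cfg$n_qc)
    colnames(qc) <- qc_ids
    conc <- cbind(conc, qc)
  }
  rownames(conc) <- compound_ids

  ## back-convert to peak areas through the internal standard:
  ## X = (V_s * C_s / M) * (I_i / I_s) * 1e-3  =>  I_i = X * I_s / k
  V_s <- 10; C_s <- 10; M_mass <- 0.5
  k <- V_s * C_s / M_mass * 1e-3
  is_sigma <- sqrt(log(1 + cfg$is_cv^2))
  is_area <- 1e6 * exp(stats::rnorm(ncol(conc), 0, is_sigma))
  names(is_area) <- colnames(conc)
  areas <- sweep(conc / k, 2, is_area, `*`)
  ft <- feature_table(areas, "peak_area")
  isp <- internal_standard_params(V_s, C_s, M_mass, is_area)

  ## annotations: descriptors tilted by trend direction
  pos_attrs <- c("fruity", "floral", "honey", "woody", "sweet")
  neg_attrs <- c("coffee", "roasted", "hay", "burnt", "spicy")
  descriptors <- lapply(trend, function(tr) {
    pool <- switch(tr, up = pos_attrs, down = neg_attrs,
                   c(pos_attrs, neg_attrs))
    sample(pool, sample(1:2, 1))
  })

  ## pathways: uniform background membership plus one pathway planted
  ## among up-trending compounds
  pathway_ids <- sprintf("P%02d", seq_len(cfg$n_pathways))
  enriched <- pathway_ids[1]
  p_bg <- min(0.5, 8 / n)   # background expected pathway size ~8
  member <- matrix(stats::runif(n * cfg$n_pathways) < p_bg, n, cfg$n_pathways,
                   dimnames = list(compound_ids, pathway_ids))
  up_ids <- compound_ids[trend == "up"]
  planted <- sample(up_ids, round(cfg$enriched_pathway_fraction_up *
                                    length(up_ids)))
  member[, enriched] <- FALSE
  member[planted, enriched] <- TRUE
  pathways <- apply(member, 1, function(r) pathway_ids[r], simplify = FALSE)

  thresholds <- 10^stats::runif(n, cfg$threshold_log10_range[1],
                                cfg$threshold_log10_range[2])
  ann <- annotation_table(compound_id = compound_ids,
                          compound_class = compound_class,
                          descriptors = descriptors,
                          odor_threshold = thresholds,
                          pathways = pathways)

  truth <- list(trend = trend, base = base, enriched_pathway = enriched,
                key_up = character(0), key_down = character(0))
  ds <- structure(list(ft = ft, ann = ann, design = design, isp = isp,
                       truth = truth),
                  class = "synth_dataset")
  plant_key_aroma(cfg, ds)
}

#' Plant key aroma compounds by threshold assignment
#'
#' Selects `n_key_up` up-trending and `n_key_down` down-trending
#' compounds and rewrites odor thresholds so that exactly those
#' compounds, among all trending compounds, have a threshold below their
#' G1-or-G4 expected stage-mean concentration: planted keys get a
#' threshold of one fifth of that stage mean (rOAV 5 at the relevant
#' stage), while the remaining trending compounds get five times their
#' maximal stage mean (rOAV at most 0.2 everywhere). The default 14 up
#' plus 7 down keys give 21 ground-truth key aroma compounds.
#'
#' @param cfg a [synth_config()].
#' @param ds a `synth_dataset` (called internally by
#'   [generate_dataset()]; exposed for testing).
#' @return The dataset with updated `ann` and `truth$key_up` /
#'   `truth$key_down`.
#' @export
plant_key_aroma <- function(cfg, ds) {
  trend <- ds$truth$trend
  base <- ds$truth$base
  up_ids <- names(trend)[trend == "up"]
  down_ids <- names(trend)[trend == "down"]
  if (cfg$n_key_up > length(up_ids) || cfg$n_key_down > length(down_ids))
    stop("not enough trending compounds to plant the requested key set",
         call. = FALSE)
  key_up <- sample(up_ids, cfg$n_key_up)
  key_down <- sample(down_ids, cfg$n_key_down)

  ann <- ds$ann
  thr <- ann$odor_threshold
  names(thr) <- ann$compound_id
  e <- cfg$effect_log2fc
  # expected stage means: up peaks at G4 (base * 2^e), down at G1 (base)
  for (id in c(up_ids, down_ids)) {
    peak <- if (trend[[id]] == "up") base[[id]] * 2^e else base[[id]]
    thr[[id]] <- if (id %in% c(key_up, key_down)) peak / 5 else peak * 5
  }
  ann$odor_threshold <- unname(thr[ann$compound_id])
  ds$ann <- ann
  ds$truth$key_up <- key_up
  ds$truth$key_down <- key_down
  ds
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synth_dataset> %d compounds, %d samples ",
                     "(%d QC), %d planted key compounds\n"),
              nrow(x$ft$values), ncol(x$ft$values),
              sum(x$design$stage == "QC"),
              length(x$truth$key_up) + length(x$truth$key_down)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `features.csv`, `annotations.csv`, `design.csv`,
#' `internal_standard.csv` and `ground_truth.json`.
#'
#' @param ds a `synth_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(ds$ft, file.path(dir, "features.csv"))
  write_annotations(ds$ann, file.path(dir, "annotations.csv"))
  write_stage_design(ds$design, file.path(dir, "design.csv"))
  utils::write.csv(
    data.frame(sample_id = names(ds$isp$is_peak_area),
               is_peak_area = unname(ds$isp$is_peak_area)),
    file.path(dir, "internal_standard.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(trend = as.list(ds$truth$trend),
         enriched_pathway = ds$truth$enriched_pathway,
         key_up = ds$truth$key_up, key_down = ds$truth$key_down),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
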