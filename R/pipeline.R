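#' Derive a per-stage seed from the global run seed
#'
#' Fixed additive offsets per analysis stage so each stage can be rerun
#' in isolation with the seed recorded in the manifest.
#'
#' @param seed global integer seed.
#' @param stage one of `"synth"`, `"opls"`, `"perm"`, `"cluster"`.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage = c("synth", "opls", "perm", "cluster")) {
  stage <- match.arg(stage)
  offset <- c(synth = 0L, opls = 1013L, perm = 2027L, cluster = 3041L)
  as.integer(seed) + offset[[stage]]
}

#' Run the full volatilomics analysis pipeline
#'
#' Orchestrates `quantify -> class totals -> PCA -> OPLS-DA ->
#' differential screen -> trend clustering -> enrichment -> rOAV/aroma`
#' on either a synthetic dataset (pass a [synth_config()]) or three
#' loaded input tables. All stage comparisons use the first stage as
#' reference (G1 vs G2, G1 vs G3, G1 vs G4 in the default design).
#' Results are written as CSV files plus a JSON manifest recording
#' parameters, seed and the count of compounds surviving each filter;
#' rerunning with an identical config reproduces the outputs.
#'
#' @param data a [synth_config()], a `synth_dataset`, or a list with
#'   elements `ft` (peak-area [feature_table()]), `ann`, `design`,
#'   `isp`.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param seed global seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @param n_perm permutations for OPLS-DA validation (default 200; 0
#'   skips).
#' @param k clusters for the trend analysis (default 8).
#' @param n_ortho,cv_folds OPLS-DA settings.
#' @param vip_min,log2fc_min,p_max differential-screen cutoffs.
#' @param alpha enrichment significance level.
#' @return A list of class `pipeline_result` with every stage's output
#'   and the manifest, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(data, out_dir = NULL, seed = 17, n_perm = 200,
                         k = 8, n_ortho = 1, cv_folds = 7, vip_min = 1,
                         log2fc_min = 1, p_max = 0.01, alpha = 0.05) {
  if (inherits(data, "synth_config")) {
    data$seed <- derive_seed(seed, "synth")
    data <- generate_dataset(data)
  }
  ds <- align_dataset(data$ft, data$ann, data$design, quiet = TRUE)

  ## quantify
  ct <- fill_missing(semi_quantify(ds$ft, data$isp))
  totals <- class_totals(ct, ds$ann, ds$design)

  ## PCA over all samples (QC included) on log concentrations
  X_all <- t(log10(ct$values))
  pca_res <- pca(X_all[, apply(X_all, 2, stats::sd) > 0, drop = FALSE],
                 scaling = "uv")

  ## stage comparisons against the first stage
  stages <- sort(setdiff(unique(ds$design$stage), "QC"))
  ref <- stages[1]
  comparisons <- paste0(ref, "_vs_", stages[-1])
  diff_results <- list(); perm_results <- list()
  for (i in seq_along(comparisons)) {
    g2 <- stages[-1][i]
    res <- compare_stages(ct, ds$design, ref, g2, n_ortho = n_ortho,
                          cv_folds = cv_folds,
                          seed = derive_seed(seed, "opls") + i,
                          vip_min = vip_min, log2fc_min = log2fc_min,
                          p_max = p_max)
    diff_results[[comparisons[i]]] <- res
    if (n_perm > 0) {
      sa <- ds$design$sample_id[ds$design$stage == ref]
      sb <- ds$design$sample_id[ds$design$stage == g2]
      X <- t(ct$values[, c(sa, sb)])
      y <- rep(c(ref, g2), c(length(sa), length(sb)))
      perm_results[[comparisons[i]]] <-
        permutation_test(X, y, n_ortho = n_ortho, cv_folds = cv_folds,
                         n_perm = n_perm,
                         seed = derive_seed(seed, "perm") + i)
    }
  }
  diff_sets <- lapply(diff_results, function(r)
    r$compound_id[r$call != "not_significant"])
  venn <- if (length(diff_sets) >= 2) venn_counts(diff_sets) else NULL
  topk <- top_k_by_fc(diff_results)

  ## trend clustering of the union of differential compounds
  diff_union <- unique(unlist(diff_sets))
  clusters <- NULL
  if (length(diff_union) > k) {
    prof <- stage_profiles(ct, ds$design)[diff_union, , drop = FALSE]
    sc <- uv_scale_profiles(prof)
    clusters <- kmeans_cluster(sc$scaled, k = k,
                               seed = derive_seed(seed, "cluster"))
  }

  ## enrichment per comparison + shared pathways
  background <- ds$ft$compound_ids
  enrich <- lapply(diff_sets, function(s)
    if (length(s)) msea(s, background, ds$ann, alpha = alpha) else NULL)
  enrich <- Filter(Negate(is.null), enrich)
  shared <- if (length(enrich) >= 2) shared_pathways(enrich) else character(0)

  ## aroma: rOAV, radar, key compounds
  roav <- compute_roav(ct, ds$ann, ds$design)
  radar <- radar_profile(roav, ds$ann)
  keys <- if (!is.null(clusters))
    screen_key_compounds(roav, clusters, ds$ann) else NULL

  manifest <- list(
    seed = seed,
    parameters = list(n_perm = n_perm, k = k, n_ortho = n_ortho,
                      cv_folds = cv_folds, vip_min = vip_min,
                      log2fc_min = log2fc_min, p_max = p_max,
                      alpha = alpha),
    counts = list(
      compounds_detected = length(ds$ft$compound_ids),
      samples = length(ds$ft$sample_ids),
      differential_per_comparison = lengths(diff_sets),
      differential_union = length(diff_union),
      clustered = if (is.null(clusters)) 0L else length(clusters$cluster),
      shared_pathways = length(shared),
      key_compounds = if (is.null(keys)) 0L else nrow(keys)),
    versions = list(volaging = as.character(utils::packageVersion("volaging")),
                    R = R.version.string))

  result <- structure(
    list(concentrations = ct, class_totals = totals, pca = pca_res,
         differential = diff_results, permutation = perm_results,
         venn = venn, top_k = topk, clusters = clusters,
         enrichment = enrich, shared_pathways = shared, roav = roav,
         radar = radar, key_compounds = keys, manifest = manifest,
         aligned = ds),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    write_pipeline_result(result, out_dir)
    return(invisible(result))
  }
  result
}

#' Write a pipeline result bundle to CSV files plus a JSON manifest
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  write_feature_table(result$concentrations,
                      file.path(out_dir, "concentrations.csv"))
  w(result$class_totals$summary, "class_totals.csv")
  w(data.frame(sample_id = rownames(result$pca$scores),
               result$pca$scores[, 1:2, drop = FALSE]), "pca_scores.csv")
  for (cmp in names(result$differential))
    w(result$differential[[cmp]], paste0("differential_", cmp, ".csv"))
  if (!is.null(result$venn))
    w(data.frame(region = names(result$venn), count = unname(result$venn)),
      "venn_regions.csv")
  w(data.frame(compound_id = result$top_k$pooled), "top_k_pooled.csv")
  if (!is.null(result$clusters))
    w(data.frame(compound_id = names(result$clusters$cluster),
                 cluster = unname(result$clusters$cluster),
                 trend = unname(result$clusters$trend[
                   result$clusters$cluster])), "clusters.csv")
  for (cmp in names(result$enrichment))
    w(result$enrichment[[cmp]], paste0("enrichment_", cmp, ".csv"))
  w(data.frame(compound_id = rownames(result$roav$roav),
               threshold = unname(result$roav$threshold),
               result$roav$roav, check.names = FALSE), "roav.csv")
  w(data.frame(category = rownames(result$radar$standardized),
               result$radar$standardized, check.names = FALSE),
    "radar.csv")
  if (!is.null(result$key_compounds)) w(result$key_compounds,
                                        "key_compounds.csv")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest$counts
  cat("<pipeline_result>\n",
      sprintf("  compounds detected: %d, samples: %d\n",
              m$compounds_detected, m$samples),
      sprintf("  differential (per comparison): %s; union %d\n",
              paste(m$differential_per_comparison, collapse = "/"),
              m$differential_union),
      sprintf("  shared enriched pathways: %d; key aroma compounds: %d\n",
              m$shared_pathways, m$key_compounds), sep = "")
  invisible(x)
}
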