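#' Internal-standard semi-quantification
#'
#' Converts peak areas to concentrations (ug/g) by ratio to a deuterated
#' internal standard spiked at a known amount:
#'
#'   X_i = (V_s * C_s / M) * (I_i / I_s) * 1e-3
#'
#' where `V_s` is the spiked volume (uL), `C_s` the standard
#' concentration (ug/mL), `M` the sample mass (g), `I_i` the compound
#' peak area and `I_s` the internal-standard peak area of the same
#' sample. The 1e-3 converts uL * ug/mL to ug, so the result is ug per
#' gram of sample. With the bench values V_s = 10 uL, C_s = 10 ug/mL,
#' M = 0.5 g, a compound whose peak area equals the standard's maps to
#' 0.2 ug/g.
#'
#' @param ft a peak-area [feature_table()].
#' @param isp an [internal_standard_params()] whose `is_peak_area`
#'   covers every sample of `ft`.
#' @return A concentration [feature_table()] (ug/g).
#' @export
semi_quantify <- function(ft, isp) {
  stopifnot(inherits(ft, "feature_table"),
            inherits(isp, "internal_standard_params"))
  if (ft$value_kind != "peak_area")
    stop("semi_quantify expects a peak-area table", call. = FALSE)
  missing_is <- setdiff(ft$sample_ids, names(isp$is_peak_area))
  if (length(missing_is))
    stop("no internal-standard area for sample(s): ",
         paste(missing_is, collapse = ", "), call. = FALSE)
  i_s <- isp$is_peak_area[ft$sample_ids]
  if (any(i_s <= 0))
    stop("internal-standard peak area must be > 0; offending sample(s): ",
         paste(ft$sample_ids[i_s <= 0], collapse = ", "), call. = FALSE)
  k <- isp$V_s * isp$C_s / isp$M_mass * 1e-3
  conc <- sweep(ft$values, 2, i_s, `/`) * k
  feature_table(conc, "concentration")
}

#' Per-class concentration totals with ANOVA and Tukey letters
#'
#' Sums concentrations within each compound class per sample, then for
#' each class runs a one-way ANOVA of the per-sample class totals across
#' time points followed by Tukey's HSD, and summarises all pairwise
#' comparisons as a compact letter display: time points sharing a letter
#' do not differ at `alpha`. QC samples are excluded.
#'
#' @param ct a concentration [feature_table()].
#' @param ann an [annotation_table()].
#' @param design a [stage_design()].
#' @param alpha significance level for the letter display (default 0.05).
#' @return A list of class `class_totals_result`: `totals` (long data
#'   frame sample x class sums), `summary` (per class and time point:
#'   mean, sd, n, Tukey letter), `anova_p` (per-class ANOVA p-value).
#' @export
class_totals <- function(ct, ann, design, alpha = 0.05) {
  stopifnot(inherits(ct, "feature_table"))
  if (ct$value_kind != "concentration")
    stop("class_totals expects concentrations; run semi_quantify first",
         call. = FALSE)
  bio <- design[design$stage != "QC", , drop = FALSE]
  keep <- intersect(ct$sample_ids, bio$sample_id)
  vals <- ct$values[, keep, drop = FALSE]
  cls <- ann$compound_class[match(rownames(vals), ann$compound_id)]
  tp <- bio$time_point[match(keep, bio$sample_id)]
  if (any(table(tp) < 2))
    stop("each time point needs at least 2 replicates", call. = FALSE)

  sums <- rowsum(vals, cls)            # class x sample
  totals <- data.frame(
    sample_id = rep(colnames(sums), each = nrow(sums)),
    time_point = rep(tp, each = nrow(sums)),
    compound_class = rep(rownames(sums), times = ncol(sums)),
    total = as.vector(sums), stringsAsFactors = FALSE)

  summaries <- list(); anova_p <- c()
  for (cl in rownames(sums)) {
    y <- sums[cl, ]
    g <- factor(tp)
    fit <- stats::aov(y ~ g)
    p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    lv <- levels(g)
    pmat <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pmat[pairs] <- tk[, "p adj"]
    pmat[pairs[, 2:1, drop = FALSE]] <- tk[, "p adj"]
    letters_by_group <- cld_insert_absorb(pmat, alpha = alpha)
    summaries[[cl]] <- data.frame(
      compound_class = cl, time_point = lv,
      mean = as.vector(tapply(y, g, mean)),
      sd = as.vector(tapply(y, g, stats::sd)),
      n = as.vector(table(g)),
      letter = letters_by_group[lv],
      stringsAsFactors = FALSE, row.names = NULL)
    anova_p[cl] <- p_anova
  }
  structure(list(totals = totals,
                 summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
                 anova_p = anova_p, alpha = alpha),
            class = "class_totals_result")
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: start from one letter covering all
#' groups; for each significantly different pair found in a column,
#' split that column into two, one without each member; absorb columns
#' that are subsets of others; assign letters `a`, `b`, ... following
#' the group order of `pmat` (or decreasing `means` when given), so the
#' alphabet is contiguous and starts at `a`. Two groups share a letter
#' if and only if their adjusted p-value is at least `alpha`.
#'
#' @param pmat symmetric matrix of pairwise adjusted p-values with group
#'   names on both dimnames.
#' @param alpha significance level.
#' @param means optional named group means used to order letters
#'   (largest mean gets `a`); default: the group order of `pmat`.
#' @return Named character vector: letter string per group.
#' @export
cld_insert_absorb <- function(pmat, alpha = 0.05, means = NULL) {
  groups <- rownames(pmat)
  n <- length(groups)
  cols <- list(rep(TRUE, n))             # logical membership vectors
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  if (nrow(sig)) {
    ord <- order(pmat[sig])              # most significant first
    sig <- sig[ord, , drop = FALSE]
  }
  for (r in seq_len(nrow(sig))) {
    i <- sig[r, 1]; j <- sig[r, 2]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb: drop any column whose members are a subset of another's
    keep <- rep(TRUE, length(cols))
    for (u in seq_along(cols)) for (v in seq_along(cols)) {
      if (u != v && keep[u] && keep[v] &&
          all(cols[[v]][cols[[u]]]) &&
          (sum(cols[[u]]) < sum(cols[[v]]) || u > v))
        keep[u] <- FALSE
    }
    cols <- cols[keep]
  }
  # order letters by decreasing mean (ties: group order)
  rank_key <- if (is.null(means)) seq_len(n) else -as.numeric(means[groups])
  col_rank <- vapply(cols, function(col) min(rank(rank_key)[col]), 0)
  cols <- cols[order(col_rank)]
  out <- vapply(seq_len(n), function(i) {
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, "")
  stats::setNames(out, groups)
}
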