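#' Stage-mean log2 fold change
#'
#' `log2(mean(stage_b) / mean(stage_a))` per compound, computed on
#' concentrations whose missing cells were filled upstream (half-minimum
#' fill keeps the ratio finite).
#'
#' @param ct a concentration [feature_table()] with no missing cells.
#' @param design a [stage_design()].
#' @param stage_a reference stage label (denominator).
#' @param stage_b comparison stage label (numerator).
#' @return Named numeric vector of log2 fold changes per compound.
#' @export
log2_fold_change <- function(ct, design, stage_a, stage_b) {
  sa <- design$sample_id[design$stage == stage_a]
  sb <- design$sample_id[design$stage == stage_b]
  sa <- intersect(sa, ct$sample_ids); sb <- intersect(sb, ct$sample_ids)
  if (!length(sa) || !length(sb))
    stop("empty stage in comparison ", stage_a, " vs ", stage_b, call. = FALSE)
  ma <- rowMeans(ct$values[, sa, drop = FALSE])
  mb <- rowMeans(ct$values[, sb, drop = FALSE])
  stats::setNames(log2(mb / ma), ct$compound_ids)
}

#' Per-compound two-sided Welch t-test between two stages
#'
#' Run on log-transformed concentrations, which symmetrises the
#' multiplicative noise of MS intensities. When both groups are
#' constant with equal values the test is undefined and p = 1 by
#' convention.
#'
#' @param ct a concentration [feature_table()] with no missing cells.
#' @param design a [stage_design()].
#' @param stage_a,stage_b stage labels to compare.
#' @param method `"welch"` (default), `"student"`, or `"wilcoxon"`.
#' @return Named numeric vector of p-values per compound.
#' @export
pairwise_test <- function(ct, design, stage_a, stage_b,
                          method = c("welch", "student", "wilcoxon")) {
  method <- match.arg(method)
  sa <- intersect(design$sample_id[design$stage == stage_a], ct$sample_ids)
  sb <- intersect(design$sample_id[design$stage == stage_b], ct$sample_ids)
  if (length(sa) < 2 || length(sb) < 2)
    stop("need at least 2 replicates per stage", call. = FALSE)
  A <- log(ct$values[, sa, drop = FALSE])
  B <- log(ct$values[, sb, drop = FALSE])
  p <- vapply(seq_len(nrow(A)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    switch(method,
           welch = stats::t.test(a, b, var.equal = FALSE)$p.value,
           student = stats::t.test(a, b, var.equal = TRUE)$p.value,
           wilcoxon = suppressWarnings(stats::wilcox.test(a, b)$p.value))
  }, 0)
  stats::setNames(p, ct$compound_ids)
}

#' Call differential volatiles from VIP, fold change and p-value
#'
#' A compound is `up` when VIP >= `vip_min`, log2FC >= `log2fc_min` and
#' p < `p_max`; `down` with log2FC <= -`log2fc_min`; otherwise
#' `not_significant`. VIP and fold-change cutoffs are inclusive, the
#' p-value cutoff strict. BH-adjusted q-values are reported alongside
#' for transparency but play no role in the calls.
#'
#' @param vip,log2fc,p aligned named numeric vectors per compound.
#' @param vip_min VIP cutoff (default 1).
#' @param log2fc_min absolute log2 fold-change cutoff (default 1).
#' @param p_max p-value cutoff (default 0.01).
#' @return A data frame of class `differential_result`: `compound_id`,
#'   `vip`, `log2fc`, `p_value`, `q_value`, `call`.
#' @export
screen_differential <- function(vip, log2fc, p, vip_min = 1,
                                log2fc_min = 1, p_max = 0.01) {
  ids <- names(log2fc)
  stopifnot(!is.null(ids), identical(ids, names(p)),
            identical(ids, names(vip)))
  call <- rep("not_significant", length(ids))
  sig <- vip >= vip_min & p < p_max
  call[sig & log2fc >= log2fc_min] <- "up"
  call[sig & log2fc <= -log2fc_min] <- "down"
  out <- data.frame(compound_id = ids, vip = unname(vip),
                    log2fc = unname(log2fc), p_value = unname(p),
                    q_value = stats::p.adjust(unname(p), "BH"),
                    call = call, stringsAsFactors = FALSE)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Run one full stage comparison
#'
#' Convenience wrapper: fits OPLS-DA on the two stages' samples
#' (UV-scaled, 1 predictive + `n_ortho` orthogonal components), computes
#' stage-mean log2 fold changes and Welch p-values, and screens.
#'
#' @param ct concentration [feature_table()] with no missing cells.
#' @param design a [stage_design()].
#' @param stage_a,stage_b stages to compare (`stage_a` is the reference).
#' @param n_ortho,cv_folds,seed passed to [opls_da()].
#' @param compute_q2 set `FALSE` to skip cross-validation when only VIP
#'   is needed.
#' @param ... passed to [screen_differential()].
#' @return A `differential_result` with the fitted model in
#'   `attr(, "model")`.
#' @export
compare_stages <- function(ct, design, stage_a, stage_b, n_ortho = 1,
                           cv_folds = 7, seed = 1, compute_q2 = TRUE, ...) {
  sa <- intersect(design$sample_id[design$stage == stage_a], ct$sample_ids)
  sb <- intersect(design$sample_id[design$stage == stage_b], ct$sample_ids)
  X <- t(ct$values[, c(sa, sb), drop = FALSE])
  y <- c(rep(stage_a, length(sa)), rep(stage_b, length(sb)))
  model <- opls_da(X, y, n_ortho = n_ortho,
                   cv_folds = if (compute_q2) cv_folds else 0, seed = seed)
  lfc <- log2_fold_change(ct, design, stage_a, stage_b)
  p <- pairwise_test(ct, design, stage_a, stage_b)
  res <- screen_differential(model$vip, lfc, p, ...)
  attr(res, "model") <- model
  attr(res, "comparison") <- c(stage_a, stage_b)
  res
}

#' Venn region counts for two or three differential sets
#'
#' @param sets named list of 2 or 3 character vectors (compound ids).
#' @return Named integer vector of exclusive region counts, named by the
#'   sets they intersect (e.g. `"A&B"`), plus `union` total.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) stop("venn_counts takes 2 or 3 sets", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm)) nm <- LETTERS[seq_len(k)]
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  counts <- apply(combos, 1, function(mask) {
    sum(apply(member, 1, function(row) all(row == mask)))
  })
  names(counts) <- apply(combos, 1, function(mask)
    paste(nm[as.logical(mask)], collapse = "&"))
  c(counts, union = length(universe))
}

#' Top-k compounds by absolute fold change per comparison
#'
#' Ranks the significant (up or down) compounds of each comparison by
#' descending |log2FC|, breaking ties by smaller p-value then
#' lexicographic compound id, keeps the first `k` (all if fewer), pools
#' the per-comparison lists into a deduplicated set, and flags compounds
#' present in every comparison's top list.
#'
#' @param results named list of `differential_result` objects.
#' @param k list length per comparison (default 20).
#' @return A list: `per_comparison` (named list of ranked data frames),
#'   `pooled` (unique compound ids), `common` (ids in all top lists).
#' @export
top_k_by_fc <- function(results, k = 20) {
  per <- lapply(results, function(res) {
    sig <- res[res$call != "not_significant", , drop = FALSE]
    ord <- order(-abs(sig$log2fc), sig$p_value, sig$compound_id)
    utils::head(sig[ord, , drop = FALSE], k)
  })
  ids <- lapply(per, `[[`, "compound_id")
  list(per_comparison = per,
       pooled = unique(unlist(ids)),
       common = Reduce(intersect, ids))
}
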