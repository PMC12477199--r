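#' Stage-mean profiles per compound
#'
#' @param ct a concentration [feature_table()] with no missing cells.
#' @param design a [stage_design()]; QC samples are excluded.
#' @param stages stage order (default the sorted non-QC stages).
#' @return Compound x stage matrix of mean concentrations.
#' @export
stage_profiles <- function(ct, design, stages = NULL) {
  bio <- design[design$stage != "QC", , drop = FALSE]
  if (is.null(stages)) stages <- sort(unique(bio$stage))
  out <- vapply(stages, function(g) {
    s <- intersect(bio$sample_id[bio$stage == g], ct$sample_ids)
    rowMeans(ct$values[, s, drop = FALSE])
  }, numeric(nrow(ct$values)))
  rownames(out) <- ct$compound_ids
  out
}

#' Unit-variance scale stage profiles by row
#'
#' Per compound: subtract the profile mean and divide by its standard
#' deviation (n - 1). Constant profiles carry no trend information and
#' are routed to a dedicated flat bucket rather than raising an error.
#'
#' @param stage_means compound x stage matrix (>= 2 stages).
#' @return A list: `scaled` (rows with variance, UV-scaled), `flat`
#'   (character ids of constant profiles).
#' @export
uv_scale_profiles <- function(stage_means) {
  if (ncol(stage_means) < 2) stop("need at least 2 stages", call. = FALSE)
  sds <- apply(stage_means, 1, stats::sd)
  flat <- rownames(stage_means)[sds == 0]
  keep <- sds > 0
  scaled <- (stage_means[keep, , drop = FALSE] -
               rowMeans(stage_means[keep, , drop = FALSE])) / sds[keep]
  list(scaled = scaled, flat = flat)
}

#' K-means clustering of UV-scaled stage profiles
#'
#' Lloyd-type K-means (Euclidean distance) with `n_init` seeded random
#' restarts, keeping the solution with the smallest within-cluster sum
#' of squares (WCSS). Cluster centroids are classified as monotone up,
#' down or other by [classify_trend()].
#'
#' @param scaled compound x stage matrix of UV-scaled profiles.
#' @param k number of clusters (default 8 expression patterns).
#' @param n_init random restarts (default 50).
#' @param seed integer seed; identical seeds give identical assignments.
#' @param trend_tol monotonicity tolerance passed to [classify_trend()].
#' @return A list of class `cluster_assignment`: `cluster` (named
#'   integer per compound), `centroids` (k x stage), `sizes`, `trend`
#'   (per cluster), `wcss`.
#' @export
kmeans_cluster <- function(scaled, k = 8, n_init = 50, seed = 1,
                           trend_tol = 0.1) {
  if (k > nrow(scaled))
    stop("k = ", k, " exceeds the number of compounds (", nrow(scaled), ")",
         call. = FALSE)
  set.seed(seed)
  uniq <- scaled[!duplicated(scaled), , drop = FALSE]
  if (nrow(uniq) < k)
    stop("fewer than k distinct profiles; reduce k", call. = FALSE)
  km <- NULL
  for (init in seq_len(n_init)) {
    centers0 <- uniq[sample(nrow(uniq), k), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(scaled, centers = centers0,
                                     iter.max = 100, algorithm = "Lloyd")),
      error = function(e) NULL)           # a restart may empty a cluster
    if (!is.null(fit) && length(unique(fit$cluster)) < k) fit <- NULL
    if (!is.null(fit) && (is.null(km) || fit$tot.withinss < km$tot.withinss))
      km <- fit
  }
  if (is.null(km)) stop("k-means failed on every restart", call. = FALSE)
  ord <- order(km$centers[, 1])          # stable cluster numbering
  relabel <- match(seq_len(k), ord)
  cluster <- relabel[km$cluster]
  names(cluster) <- rownames(scaled)
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  structure(list(cluster = cluster, centroids = centroids,
                 sizes = as.vector(table(factor(cluster, seq_len(k)))),
                 trend = apply(centroids, 1, classify_trend,
                               tol = trend_tol),
                 wcss = km$tot.withinss, k = k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d, %d compounds, WCSS = %.3f\n",
              x$k, length(x$cluster), x$wcss))
  print(data.frame(cluster = seq_len(x$k), size = x$sizes,
                   trend = unname(x$trend)))
  invisible(x)
}

#' Classify a centroid's trend across stages
#'
#' `up` when the centroid is non-decreasing across stages and rises by
#' more than `tol` in total; `down` symmetrically; everything else
#' (transient peaks, oscillations, near-flat profiles) is `other`. The
#' default tolerance of 0.1 scaled units keeps noise-level wiggles out
#' of the monotone classes.
#'
#' @param centroid numeric vector over >= 2 stages.
#' @param tol minimal total rise/fall in scaled units (default 0.1).
#' @return `"up"`, `"down"` or `"other"`.
#' @export
classify_trend <- function(centroid, tol = 0.1) {
  d <- diff(centroid)
  total <- centroid[length(centroid)] - centroid[1]
  if (all(d >= 0) && total > tol) return("up")
  if (all(d <= 0) && total < -tol) return("down")
  "other"
}

#' Tally aroma descriptors over a compound set
#'
#' Each compound contributes one count to every descriptor it carries;
#' compounds without descriptors contribute nothing.
#'
#' @param compound_ids character vector of compounds.
#' @param ann an [annotation_table()].
#' @return Named integer vector descriptor -> count, sorted decreasing.
#' @export
attribute_tally <- function(compound_ids, ann) {
  idx <- match(compound_ids, ann$compound_id)
  idx <- idx[!is.na(idx)]
  desc <- unlist(ann$descriptors[idx])
  if (!length(desc)) return(stats::setNames(integer(0), character(0)))
  sort(table(desc), decreasing = TRUE) |> c()
}
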