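#' Relative odor activity values per stage
#'
#' rOAV = stage-mean concentration / odor threshold, both in ug/g. A
#' compound with rOAV >= 1 is flagged a key aroma contributor and one
#' with rOAV >= 10 a pronounced contributor. Compounds without a
#' threshold are carried with missing rOAV and excluded from category
#' averages downstream.
#'
#' @param ct a concentration [feature_table()] with no missing cells.
#' @param ann an [annotation_table()] supplying `odor_threshold`.
#' @param design a [stage_design()]; QC samples are excluded.
#' @param stages stage order (default sorted non-QC stages).
#' @return A list of class `roav_table`: `concentration` (compound x
#'   stage means), `roav` (same shape, `NA` where the threshold is
#'   missing), `threshold`, `key` (rOAV >= 1 at any stage), `pronounced`
#'   (rOAV >= 10 at any stage).
#' @export
compute_roav <- function(ct, ann, design, stages = NULL) {
  prof <- stage_profiles(ct, design, stages)
  thr <- ann$odor_threshold[match(rownames(prof), ann$compound_id)]
  names(thr) <- rownames(prof)
  roav <- prof / thr
  n_missing <- sum(is.na(thr))
  if (n_missing)
    message("compute_roav: ", n_missing,
            " compound(s) lack an odor threshold; rOAV left missing")
  structure(list(concentration = prof, roav = roav, threshold = thr,
                 key = apply(roav >= 1, 1, any),
                 pronounced = apply(roav >= 10, 1, any)),
            class = "roav_table")
}

#' @export
print.roav_table <- function(x, ...) {
  cat(sprintf("<roav_table> %d compounds x %d stages; %d key (rOAV >= 1), %d pronounced (rOAV >= 10)\n",
              nrow(x$roav), ncol(x$roav),
              sum(x$key, na.rm = TRUE), sum(x$pronounced, na.rm = TRUE)))
  invisible(x)
}

#' Aroma-category radar profile across stages
#'
#' For each aroma category the raw stage score is the mean rOAV over the
#' compounds carrying a matching descriptor (a compound with several
#' matching descriptors contributes to each matching category; compounds
#' with missing rOAV are excluded). Each category's scores are then
#' UV-standardised across stages (mean 0, SD 1) so categories of very
#' different absolute odor activity can share one radar plot. Categories
#' with no member compounds are dropped with a warning; a category whose
#' raw score is constant across stages (no trend to standardise) gets a
#' zero profile.
#'
#' @param roav a `roav_table` from [compute_roav()].
#' @param ann an [annotation_table()].
#' @param categories ordered character vector of category labels; the
#'   default is the ten cigar aroma attributes.
#' @return A list of class `radar_profile`: `raw` and `standardized`
#'   (category x stage matrices).
#' @export
radar_profile <- function(roav, ann,
                          categories = c("fruity", "floral", "honey",
                                         "woody", "sweet", "coffee",
                                         "roasted", "hay", "burnt",
                                         "spicy")) {
  if (ncol(roav$roav) < 2)
    stop("UV standardisation needs at least 2 stages", call. = FALSE)
  desc <- ann$descriptors[match(rownames(roav$roav), ann$compound_id)]
  raw <- t(vapply(categories, function(cat) {
    member <- vapply(desc, function(d) cat %in% d, TRUE)
    member[is.na(roav$threshold)] <- FALSE
    if (!any(member)) return(rep(NA_real_, ncol(roav$roav)))
    colMeans(roav$roav[member, , drop = FALSE])
  }, numeric(ncol(roav$roav))))
  empty <- rowSums(!is.na(raw)) == 0
  if (any(empty)) {
    warning("dropping categories with no member compounds: ",
            paste(categories[empty], collapse = ", "))
    raw <- raw[!empty, , drop = FALSE]
  }
  std <- t(apply(raw, 1, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(std) <- dimnames(raw)
  structure(list(raw = raw, standardized = std), class = "radar_profile")
}

#' Screen key aroma-active compounds
#'
#' Selects, among compounds whose trend-cluster centroid is monotone up
#' or down, those with rOAV strictly greater than 1 at the first or last
#' stage (typically G1 or G4): compounds both consistently changing and
#' odor-active at one end of the time course. Direction comes from the
#' compound's cluster trend.
#'
#' @param roav a `roav_table`.
#' @param clusters a `cluster_assignment` from [kmeans_cluster()].
#' @param ann optional [annotation_table()] to attach class and
#'   descriptors.
#' @param roav_min rOAV cutoff, strict (default 1).
#' @param stages pair of stage labels to test (default first and last
#'   column of the rOAV table).
#' @return A data frame of class `key_compound_set`: `compound_id`,
#'   `direction`, `cluster`, `roav_first`, `roav_last`, and, when `ann`
#'   is given, `compound_class` and `descriptors`.
#' @export
screen_key_compounds <- function(roav, clusters, ann = NULL, roav_min = 1,
                                 stages = NULL) {
  stage_labels <- colnames(roav$roav)
  if (is.null(stages)) stages <- stage_labels[c(1, length(stage_labels))]
  ids <- intersect(names(clusters$cluster), rownames(roav$roav))
  trend <- unname(clusters$trend[clusters$cluster[ids]])
  r1 <- roav$roav[ids, stages[1]]
  r2 <- roav$roav[ids, stages[2]]
  active <- !is.na(r1) & !is.na(r2) & (r1 > roav_min | r2 > roav_min)
  keep <- trend %in% c("up", "down") & active
  out <- data.frame(compound_id = ids[keep],
                    direction = trend[keep],
                    cluster = unname(clusters$cluster[ids[keep]]),
                    roav_first = unname(r1[keep]),
                    roav_last = unname(r2[keep]),
                    stringsAsFactors = FALSE)
  if (!is.null(ann)) {
    m <- match(out$compound_id, ann$compound_id)
    out$compound_class <- ann$compound_class[m]
    out$descriptors <- vapply(ann$descriptors[m], paste, "", collapse = ";")
  }
  out <- out[order(out$direction, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("key_compound_set", "data.frame")
  out
}
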