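#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least `k` pathway members when `n` compounds are drawn without
#' replacement from a background of `N` compounds of which `K` belong to
#' the pathway.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K pathway compounds in the background.
#' @param n drawn (differential) compounds.
#' @param N background size.
#' @return The tail probability in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (K > N || n > N || k < 0 || k > min(K, n))
    stop("inconsistent hypergeometric arguments (k=", k, ", K=", K,
         ", n=", n, ", N=", N, ")", call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Metabolite set enrichment analysis (hypergeometric MSEA)
#'
#' Over-representation test of a differential compound set against a
#' compound-to-pathway map. The background defaults to all detected,
#' annotated compounds. Pathways with no background member are skipped;
#' results are sorted by ascending p-value; the significance flag uses
#' the raw p-value at `alpha` and a BH-adjusted column is reported
#' alongside.
#'
#' @param diff_set character vector of differential compound ids (must
#'   be a subset of `background`).
#' @param background character vector of background compound ids.
#' @param pathway_map named list pathway_id -> character vector of
#'   member compound ids, or an [annotation_table()] (its `pathways`
#'   column is inverted into the map).
#' @param alpha significance level (default 0.05).
#' @return A data frame of class `enrichment_result`: `pathway_id`, `N`,
#'   `K`, `n`, `k`, `p_value`, `q_value`, `significant`.
#' @export
msea <- function(diff_set, background, pathway_map, alpha = 0.05) {
  if (inherits(pathway_map, "annotation_table"))
    pathway_map <- invert_pathways(pathway_map)
  extra <- setdiff(diff_set, background)
  if (length(extra))
    stop("differential compounds missing from the background: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  if (!length(diff_set))
    warning("empty differential set; no enrichment computed")
  N <- length(background)
  n <- length(diff_set)
  rows <- lapply(names(pathway_map), function(pw) {
    members <- intersect(pathway_map[[pw]], background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, diff_set))
    data.frame(pathway_id = pw, N = N, K = K, n = n, k = k,
               p_value = hypergeom_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway_id = character(0), N = integer(0),
                      K = integer(0), n = integer(0), k = integer(0),
                      p_value = numeric(0))
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# annotation_table pathways column -> pathway_id -> member ids map
invert_pathways <- function(ann) {
  pairs <- data.frame(
    compound_id = rep(ann$compound_id, lengths(ann$pathways)),
    pathway_id = unlist(ann$pathways), stringsAsFactors = FALSE)
  split(pairs$compound_id, pairs$pathway_id)
}

#' Read a two-column compound-to-pathway map
#'
#' Delimited text with columns `compound_id`, `pathway_id`; one row per
#' membership.
#'
#' @param path file path.
#' @param delim delimiter; `NULL` auto-detects comma/tab.
#' @return Named list pathway_id -> character vector of compound ids.
#' @export
read_pathway_map <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE)
  split(as.character(df$compound_id), as.character(df$pathway_id))
}

#' Pathways significant in every comparison
#'
#' @param results named list of `enrichment_result` objects (>= 2).
#' @return Character vector: intersection of the significant pathway
#'   sets.
#' @export
shared_pathways <- function(results) {
  if (length(results) < 2)
    stop("need at least 2 comparisons", call. = FALSE)
  Reduce(intersect, lapply(results, function(r)
    r$pathway_id[r$significant]))
}
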