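#' Construct a feature table
#'
#' A feature table holds a compound-by-sample matrix of non-negative
#' abundances, either raw GC-MS peak areas (arbitrary units) or
#' concentrations (ug/g) after internal-standard semi-quantification.
#' Unobserved cells are `NA` (missing), never zero; see
#' [fill_missing()] for the half-minimum fill applied before any log
#' transform.
#'
#' @param values numeric matrix, compounds in rows, samples in columns.
#'   Row and column names are the compound and sample identifiers.
#' @param value_kind `"peak_area"` or `"concentration"`.
#' @return An object of class `feature_table`: a list with elements
#'   `values`, `value_kind`, `compound_ids`, `sample_ids`.
#' @export
feature_table <- function(values, value_kind = c("peak_area", "concentration")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have compound row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate compound ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("negative abundance values are not allowed", call. = FALSE)
  structure(
    list(values = values, value_kind = value_kind,
         compound_ids = rownames(values), sample_ids = colnames(values)),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d compounds x %d samples (%s), %d missing cells\n",
              nrow(x$values), ncol(x$values), x$value_kind,
              sum(is.na(x$values))))
  invisible(x)
}

# Sniff comma vs tab from the header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' Read a compound-by-sample feature table
#'
#' Expects delimited text (comma or tab, auto-detected) with a header row
#' of sample ids and the first column holding compound ids. Empty cells
#' and the strings `NA`/`nan` become missing values, not zeros.
#'
#' @param path file path.
#' @param value_kind `"peak_area"` or `"concentration"`.
#' @param delim field delimiter; `NULL` (default) auto-detects.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path,
                               value_kind = c("peak_area", "concentration"),
                               delim = NULL) {
  value_kind <- match.arg(value_kind)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "nan", ""), quote = "\"",
                          comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate compound ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  feature_table(m, value_kind)
}

#' Write a feature table to delimited text
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, delim = ",") {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(compound_id = ft$compound_ids, ft$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a compound annotation table
#'
#' Columns: `compound_id`, `compound_class`, `descriptors`,
#' `odor_threshold` (ug/g, may be empty), `pathways`. Multi-valued
#' fields (`descriptors`, `pathways`) use `sub_delim` between entries.
#' Descriptor and pathway strings are trimmed and lower-cased.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` auto-detects comma/tab.
#' @param sub_delim delimiter inside multi-valued fields (default `";"`).
#' @return An object of class `annotation_table`: a data frame with
#'   list-columns `descriptors` and `pathways` and numeric
#'   `odor_threshold` (`NA` when absent).
#' @export
read_annotations <- function(path, delim = NULL, sub_delim = ";") {
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  annotation_table(
    compound_id = as.character(df$compound_id),
    compound_class = as.character(df$compound_class),
    descriptors = split_multi(df$descriptors, sub_delim),
    odor_threshold = as.numeric(df$odor_threshold),
    pathways = split_multi(df$pathways, sub_delim))
}

split_multi <- function(x, sub_delim) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    v <- tolower(trimws(strsplit(s, sub_delim, fixed = TRUE)[[1L]]))
    v[nzchar(v)]
  })
}

#' Construct an annotation table
#'
#' @param compound_id character vector of unique compound ids.
#' @param compound_class character vector of class labels (terpenoids,
#'   esters, heterocyclics, ketones, aldehydes, others, ...).
#' @param descriptors list of character vectors of aroma descriptors.
#' @param odor_threshold numeric vector of odor thresholds (ug/g); `NA`
#'   where unknown; must be strictly positive when present.
#' @param pathways list of character vectors of pathway ids.
#' @return An `annotation_table` data frame.
#' @export
annotation_table <- function(compound_id, compound_class,
                             descriptors = NULL, odor_threshold = NA_real_,
                             pathways = NULL) {
  n <- length(compound_id)
  if (anyDuplicated(compound_id))
    stop("duplicate compound ids in annotations", call. = FALSE)
  if (is.null(descriptors)) descriptors <- rep(list(character(0)), n)
  if (is.null(pathways)) pathways <- rep(list(character(0)), n)
  odor_threshold <- rep_len(as.numeric(odor_threshold), n)
  bad <- !is.na(odor_threshold) & odor_threshold <= 0
  if (any(bad))
    stop("non-positive odor threshold for: ",
         paste(compound_id[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(compound_id = as.character(compound_id),
                    compound_class = as.character(compound_class),
                    odor_threshold = odor_threshold,
                    stringsAsFactors = FALSE)
  out$descriptors <- descriptors
  out$pathways <- pathways
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Write an annotation table
#' @param ann an [annotation_table()].
#' @param path output path.
#' @param delim field delimiter; `sub_delim` joins multi-valued fields.
#' @param sub_delim delimiter inside multi-valued fields.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, delim = ",", sub_delim = ";") {
  df <- data.frame(
    compound_id = ann$compound_id,
    compound_class = ann$compound_class,
    descriptors = vapply(ann$descriptors, paste, "", collapse = sub_delim),
    odor_threshold = ann$odor_threshold,
    pathways = vapply(ann$pathways, paste, "", collapse = sub_delim),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Construct a stage design
#'
#' Maps every sample to a time point (S0..S5 style), an aging stage
#' (G1..G4) or the QC flag, and a replicate index. Pooled QC samples use
#' `stage = "QC"`.
#'
#' @param sample_id,time_point,stage character vectors, one entry per sample.
#' @param replicate_index integer replicate number within time point.
#' @return A `stage_design` data frame.
#' @export
stage_design <- function(sample_id, time_point, stage, replicate_index) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in design", call. = FALSE)
  df <- data.frame(sample_id = as.character(sample_id),
                   time_point = as.character(time_point),
                   stage = as.character(stage),
                   replicate_index = as.integer(replicate_index),
                   stringsAsFactors = FALSE)
  tab <- table(df$stage[df$stage != "QC"])
  if (length(tab) && any(tab < 2))
    stop("each non-QC stage needs at least 2 samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  class(df) <- c("stage_design", "data.frame")
  df
}

#' Read a stage design table
#'
#' Delimited text with columns `sample_id`, `time_point`, `stage`,
#' `replicate_index`.
#'
#' @param path file path.
#' @param delim delimiter; `NULL` auto-detects.
#' @return A [stage_design()].
#' @export
read_stage_design <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  stage_design(df$sample_id, df$time_point, df$stage, df$replicate_index)
}

#' Write a stage design table
#' @param design a [stage_design()].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_stage_design <- function(design, path, delim = ",") {
  utils::write.table(as.data.frame(design), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Internal standard parameters for semi-quantification
#'
#' @param V_s volume of internal standard spiked (uL).
#' @param C_s concentration of the internal standard solution (ug/mL).
#' @param M_mass sample mass (g).
#' @param is_peak_area named numeric vector: internal-standard peak area
#'   per sample; all strictly positive.
#' @return An `internal_standard_params` object.
#' @export
internal_standard_params <- function(V_s, C_s, M_mass, is_peak_area) {
  if (V_s <= 0 || C_s <= 0 || M_mass <= 0)
    stop("V_s, C_s and M_mass must be strictly positive", call. = FALSE)
  if (is.null(names(is_peak_area)))
    stop("`is_peak_area` must be named by sample id", call. = FALSE)
  structure(list(V_s = V_s, C_s = C_s, M_mass = M_mass,
                 is_peak_area = is_peak_area),
            class = "internal_standard_params")
}

#' Align feature table, annotations and design
#'
#' Intersects the compound universe of the feature table with the
#' annotation table and the sample universe with the design, dropping
#' (with a message) whatever is absent from one side. Idempotent.
#'
#' @param ft a [feature_table()].
#' @param ann an [annotation_table()].
#' @param design a [stage_design()].
#' @param quiet suppress drop messages.
#' @return A list of class `aligned_dataset` with elements `ft`, `ann`,
#'   `design` (all restricted to the common universe, in feature-table
#'   order) and `dropped` (counts per side).
#' @export
align_dataset <- function(ft, ann, design, quiet = FALSE) {
  keep_cpd <- intersect(ft$compound_ids, ann$compound_id)
  keep_smp <- intersect(ft$sample_ids, design$sample_id)
  if (length(keep_cpd) == 0L)
    stop("no compounds shared between feature table and annotations",
         call. = FALSE)
  if (length(keep_smp) == 0L)
    stop("no samples shared between feature table and design", call. = FALSE)
  dropped <- c(
    compounds_unannotated = length(setdiff(ft$compound_ids, keep_cpd)),
    annotations_unused    = length(setdiff(ann$compound_id, keep_cpd)),
    samples_undesigned    = length(setdiff(ft$sample_ids, keep_smp)),
    design_rows_unused    = length(setdiff(design$sample_id, keep_smp)))
  if (!quiet && any(dropped > 0))
    message("align: dropped ",
            paste(sprintf("%s=%d", names(dropped)[dropped > 0],
                          dropped[dropped > 0]), collapse = ", "))
  ft2 <- feature_table(ft$values[keep_cpd, keep_smp, drop = FALSE],
                       ft$value_kind)
  ann2 <- ann[match(keep_cpd, ann$compound_id), , drop = FALSE]
  rownames(ann2) <- NULL
  design2 <- design[match(keep_smp, design$sample_id), , drop = FALSE]
  rownames(design2) <- NULL
  structure(list(ft = ft2, ann = ann2, design = design2, dropped = dropped),
            class = "aligned_dataset")
}

#' Fill missing abundances with half the per-compound minimum
#'
#' Unobserved abundances are treated as below detection, not absent:
#' each missing cell is replaced by `fraction` (default one half) of the
#' smallest positive observed value of that compound, the common
#' metabolomics convention that keeps subsequent log fold changes
#' finite. Applied once, before any log transform. A compound with no
#' positive observation falls back to `fraction` times the global
#' minimum positive value.
#'
#' @param ft a [feature_table()].
#' @param fraction multiplier on the per-compound minimum (default 0.5).
#' @return A `feature_table` with no missing cells.
#' @export
fill_missing <- function(ft, fraction = 0.5) {
  m <- ft$values
  if (!anyNA(m) && all(m > 0)) return(ft)
  global_min <- suppressWarnings(min(m[m > 0], na.rm = TRUE))
  if (!is.finite(global_min)) global_min <- 1
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    need <- is.na(row) | row == 0
    if (!any(need)) next
    pos <- row[!is.na(row) & row > 0]
    fill <- fraction * if (length(pos)) min(pos) else global_min
    m[i, need] <- fill
  }
  feature_table(m, ft$value_kind)
}
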