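#' PCA score plot
#'
#' Scatter of the first two principal components, coloured by stage;
#' pooled QC samples should cluster tightly near the centre when the
#' analytical run is stable.
#'
#' @param pca_res a `pca_result`.
#' @param design a [stage_design()].
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(pca_res, design) {
  df <- data.frame(sample_id = rownames(pca_res$scores),
                   PC1 = pca_res$scores[, 1], PC2 = pca_res$scores[, 2],
                   stringsAsFactors = FALSE)
  df$stage <- design$stage[match(df$sample_id, design$sample_id)]
  evr <- 100 * pca_res$explained_variance_ratio
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.2f%%)", evr[1]),
                  y = sprintf("PC2 (%.2f%%)", evr[2])) +
    ggplot2::theme_minimal()
}

#' Volcano plot of one stage comparison
#'
#' @param diff_res a `differential_result`.
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff_res) {
  ggplot2::ggplot(diff_res,
                  ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                               colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2980b9",
                                            not_significant = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Trend-cluster centroid profiles
#'
#' One line per cluster centroid across stages, faceted by cluster with
#' its monotone-trend label.
#'
#' @param clusters a `cluster_assignment`.
#' @return A ggplot object.
#' @export
plot_cluster_trends <- function(clusters) {
  cen <- clusters$centroids
  df <- data.frame(
    cluster = rep(seq_len(nrow(cen)), ncol(cen)),
    stage = rep(colnames(cen), each = nrow(cen)),
    value = as.vector(cen), stringsAsFactors = FALSE)
  df$label <- sprintf("cluster %d (%s, n=%d)", df$cluster,
                      clusters$trend[df$cluster], clusters$sizes[df$cluster])
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$value,
                                   group = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "stage", y = "UV-scaled stage mean") +
    ggplot2::theme_minimal()
}
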