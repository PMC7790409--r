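#' Plot a fitted VAF mixture
#'
#' VAF histogram with cluster assignments colored and cluster means marked;
#' the highest-VAF (clonal) cluster is the leftmost legend entry.
#'
#' @param object A `vaf_clusters` object.
#' @param alt_counts,depths The counts the model was fitted to.
#' @param binwidth Histogram bin width.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vaf_clusters <- function(object, alt_counts, depths, binwidth = 0.02, ...) {
  df <- tibble(vaf = alt_counts / depths,
               cluster = factor(object$assignment))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vaf, fill = .data$cluster)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$clusters$mean_vaf, linetype = 2) +
    ggplot2::labs(x = "variant allele frequency", y = "variants",
                  fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot per-group transition frequencies at C/G and hotspot C/G
#'
#' @param summary A [spectrum_summary()] result.
#' @return A ggplot object (grouped bars, pooled frequencies).
#' @export
plot_spectrum <- function(summary) {
  df <- summary$per_group |>
    select("group", total_cg = "freq_ts_cg", hotspot_cg = "freq_ts_cg_hotspot") |>
    tidyr::pivot_longer(-"group", names_to = "denominator", values_to = "frequency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$denominator, y = .data$frequency,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "transition frequency per eligible base") +
    ggplot2::theme_minimal()
}

#' Plot pooled clonal/subclonal proportions per group
#'
#' @param ith An `ith_test` object.
#' @return A ggplot object (stacked proportions).
#' @export
plot_clonality <- function(ith) {
  df <- as_tibble(ith$pooled, rownames = "group") |>
    tidyr::pivot_longer(-"group", names_to = "label", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n, fill = .data$label)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "proportion of variants", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cancer-gene presence/absence matrix
#'
#' @param matrix A `gene_matrix` object.
#' @return A ggplot object (tiles colored by most severe consequence).
#' @export
plot_gene_matrix <- function(matrix) {
  ggplot2::ggplot(matrix$cells,
                  ggplot2::aes(x = .data$sample, y = .data$gene,
                               fill = .data$consequence)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "most severe\nconsequence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
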