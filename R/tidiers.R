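#' Tidy a fitted VAF mixture
#'
#' @param x A `vaf_clusters` object.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `mean_vaf`, `weight`,
#'   `n_variants`, and `label` if clonality has been assigned.
#' @exportS3Method generics::tidy
tidy.vaf_clusters <- function(x, ...) {
  x$clusters
}

#' One-row summary of a fitted VAF mixture
#'
#' @param x A `vaf_clusters` object.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, `loglik`, `bic`, and
#'   `subclonal_proportion` when labeled.
#' @exportS3Method generics::glance
glance.vaf_clusters <- function(x, ...) {
  tibble(k = x$k, n = x$n, loglik = x$loglik, bic = x$bic,
         subclonal_proportion = x$subclonal_proportion %||% NA_real_)
}

#' Tidy an intratumor-heterogeneity comparison
#'
#' @param x An `ith_test` object.
#' @param ... Unused.
#' @return Per-tumor clonal/subclonal counts and proportions.
#' @exportS3Method generics::tidy
tidy.ith_test <- function(x, ...) {
  x$per_tumor
}

#' One-row summary of an intratumor-heterogeneity comparison
#'
#' @param x An `ith_test` object.
#' @param ... Unused.
#' @return Tibble with pooled proportions, odds ratio and Fisher p-value.
#' @exportS3Method generics::glance
glance.ith_test <- function(x, ...) {
  tibble(subclonal_a = x$subclonal_proportion[1],
         subclonal_b = x$subclonal_proportion[2],
         odds_ratio = x$odds_ratio, p_value = x$p_value)
}

#' Tidy a spectrum summary
#'
#' @param x A `spectrum_summary` object.
#' @param ... Unused.
#' @return The per-sample count/frequency tibble.
#' @exportS3Method generics::tidy
tidy.spectrum_summary <- function(x, ...) {
  x$per_sample
}

#' One-row-per-group summary of a spectrum summary
#'
#' @param x A `spectrum_summary` object.
#' @param ... Unused.
#' @return The pooled per-group tibble.
#' @exportS3Method generics::glance
glance.spectrum_summary <- function(x, ...) {
  x$per_group
}
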