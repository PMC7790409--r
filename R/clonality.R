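#' Filter variants before VAF clustering
#'
#' Keeps variants with read support of at least `min_depth` (statistical
#' robustness of the VAF estimate), VAF at most `max_vaf` (removing residual
#' germline variants), and loci outside any copy-number-altered region (the
#' binomial VAF model assumes copy-neutral diploid loci). Exclusions are
#' tallied by the first matching reason in the fixed order
#' depth -> vaf -> cnv. The filter is idempotent.
#'
#' @param variants Per-tumor variant table.
#' @param cnv_regions Tibble of 0-based half-open intervals
#'   (`chrom`/`start`/`end`), or `NULL`.
#' @param min_depth Minimum total reads (default 100).
#' @param max_vaf Maximum VAF (default 0.8).
#' @return List with `kept` and `excluded` (the latter with a `reason`
#'   column).
#' @export
filter_for_clustering <- function(variants, cnv_regions = NULL,
                                  min_depth = 100L, max_vaf = 0.8) {
  if (nrow(variants) == 0L) {
    return(list(kept = variants, excluded = mutate(variants, reason = character(0))))
  }
  in_cnv <- rep(FALSE, nrow(variants))
  if (!is.null(cnv_regions) && nrow(cnv_regions) > 0L) {
    for (i in seq_len(nrow(cnv_regions))) {
      cv <- cnv_regions[i, ]
      in_cnv <- in_cnv | (variants$chrom == cv$chrom &
                            variants$pos > cv$start & variants$pos <= cv$end)
    }
  }
  reason <- case_when(
    is.na(variants$vaf) | variants$depth < min_depth ~ "low_depth",
    variants$vaf > max_vaf ~ "high_vaf",
    in_cnv ~ "in_cnv",
    TRUE ~ "kept"
  )
  list(kept = variants[reason == "kept", , drop = FALSE],
       excluded = mutate(variants[reason != "kept", , drop = FALSE],
                         reason = reason[reason != "kept"]))
}

# One EM run from a given initialization. Returns parameters, log-likelihood
# trace and responsibilities. The likelihood is exact binomial; the M-step
# pools alt/depth weighted by responsibilities. The binomial coefficient is
# precomputed once; the E-step is a single outer-product per iteration.
em_binom_mix <- function(alt, depth, p0, w0, max_iter = 500L, tol = 1e-7,
                         lch = lchoose(depth, alt)) {
  n <- length(alt); k <- length(p0)
  p <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
  w <- w0 / sum(w0)
  ref <- depth - alt
  ll_old <- -Inf; ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    logmat <- lch + outer(alt, log(p)) + outer(ref, log1p(-p)) +
      rep(log(w), each = n)
    m <- logmat[cbind(seq_len(n), max.col(logmat))]
    lse <- m + log(rowSums(exp(logmat - m)))
    ll <- sum(lse)
    r <- exp(logmat - lse)
    w <- colMeans(r)
    p <- pmin(pmax(colSums(r * alt) / pmax(colSums(r * depth), 1e-12), 1e-6), 1 - 1e-6)
    ll_trace <- c(ll_trace, ll)
    if (ll < ll_old - 1e-6) abort("EM log-likelihood decreased")  # invariant
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(p = p, w = w, loglik = ll, resp = r, ll_trace = ll_trace)
}

# k-means++-style spread initialization on the observed VAFs.
kpp_init <- function(vaf, k) {
  centers <- vaf[sample.int(length(vaf), 1L)]
  while (length(centers) < k) {
    d2 <- do.call(pmin, lapply(centers, function(cc) (vaf - cc)^2))
    if (sum(d2) <= 0) {
      centers <- c(centers, vaf[sample.int(length(vaf), 1L)])
    } else {
      centers <- c(centers, vaf[sample.int(length(vaf), 1L, prob = d2)])
    }
  }
  centers
}

#' Fit a binomial mixture to per-variant read counts
#'
#' Models `alt_count ~ Binomial(depth, p_j)` with cluster-specific success
#' probabilities (mean VAFs) and mixing weights, fit by
#' expectation-maximization for each k in `1..k_max` with `restarts` seeded
#' k-means++-style initializations, keeping the best likelihood. k is chosen
#' by the Bayesian information criterion; components whose means differ by
#' less than `merge_tol` are merged afterwards. Given the same seed the fit
#' is deterministic and invariant to the order of the input (variants are
#' sorted internally before initialization).
#'
#' @param alt_counts,depths Integer vectors of per-variant read counts.
#' @param k_max Largest number of clusters considered (default 6).
#' @param seed Integer seed controlling the restarts.
#' @param restarts Initializations per k (default 10).
#' @param merge_tol Minimum separation of cluster means (default 0.02).
#' @return A `vaf_clusters` object: `clusters` tibble (ordered by decreasing
#'   mean VAF), per-variant `assignment` and `posterior`, `k`, `loglik`,
#'   `bic`, and the per-k `bic_table`.
#' @export
fit_vaf_clusters <- function(alt_counts, depths, k_max = 6L, seed = 1L,
                             restarts = 10L, merge_tol = 0.02) {
  n <- length(alt_counts)
  if (n < 10L) abort("fewer than 10 variants after filtering; report this tumor unclustered")
  if (k_max < 1L) abort("k_max must be >= 1")
  ord <- order(depths, alt_counts)
  alt <- as.integer(alt_counts)[ord]
  depth <- as.integer(depths)[ord]
  vaf <- alt / depth
  lch <- lchoose(depth, alt)

  withr::with_seed(as.integer(seed), {
    fits <- vector("list", k_max)
    bic_tbl <- tibble(k = integer(), loglik = double(), bic = double())
    for (k in seq_len(k_max)) {
      best <- NULL
      n_try <- if (k == 1L) 1L else restarts
      for (r in seq_len(n_try)) {
        p0 <- if (k == 1L) mean(vaf) else kpp_init(vaf, k)
        fit <- em_binom_mix(alt, depth, p0, rep(1 / k, k), lch = lch)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      npar <- 2L * k - 1L
      bic_tbl <- bind_rows(bic_tbl,
                           tibble(k = k, loglik = best$loglik,
                                  bic = -2 * best$loglik + npar * log(n)))
      fits[[k]] <- best
    }
    k_sel <- bic_tbl$k[which.min(bic_tbl$bic)]
    fit <- fits[[k_sel]]

    # merge near-identical components, then reassign by posterior
    p <- fit$p; w <- fit$w
    repeat {
      if (length(p) == 1L) break
      dmat <- abs(outer(p, p, "-")); diag(dmat) <- Inf
      if (min(dmat) >= merge_tol) break
      ij <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      i <- min(ij); j <- max(ij)
      p[i] <- (w[i] * p[i] + w[j] * p[j]) / (w[i] + w[j])
      w[i] <- w[i] + w[j]
      p <- p[-j]; w <- w[-j]
    }
    k_eff <- length(p)
    logmat <- matrix(sapply(seq_len(k_eff), function(j)
      log(w[j]) + dbinom(alt, depth, p[j], log = TRUE)), nrow = n)
    m <- apply(logmat, 1, max)
    post <- exp(logmat - (m + log(rowSums(exp(logmat - m)))))
    assign_sorted <- max.col(post, ties.method = "first")

    # order clusters by decreasing mean VAF; cluster 1 = highest
    ord_k <- order(p, decreasing = TRUE)
    relabel <- match(seq_len(k_eff), ord_k)
    assign_sorted <- relabel[assign_sorted]
    post <- post[, ord_k, drop = FALSE]
    p <- p[ord_k]; w <- w[ord_k]

    assignment <- integer(n); assignment[ord] <- assign_sorted
    posterior <- matrix(NA_real_, n, k_eff); posterior[ord, ] <- post

    clusters <- tibble(cluster = seq_len(k_eff), mean_vaf = p, weight = w,
                       n_variants = as.integer(tabulate(assign_sorted, k_eff)))
    structure(list(clusters = clusters, assignment = assignment,
                   posterior = posterior, k = k_eff, loglik = fit$loglik,
                   bic = min(bic_tbl$bic), bic_table = bic_tbl,
                   n = n, merge_tol = merge_tol, labels = NULL),
              class = "vaf_clusters")
  })
}

#' @export
print.vaf_clusters <- function(x, ...) {
  cat(sprintf("<vaf_clusters> k = %d over %d variants (BIC %.1f)\n", x$k, x$n, x$bic))
  print(x$clusters)
  if (!is.null(x$labels)) {
    cat(sprintf("subclonal proportion: %.3f\n", x$subclonal_proportion))
  }
  invisible(x)
}

#' Label clusters clonal vs subclonal
#'
#' The cluster with the highest mean VAF is labeled `clonal` (the early
#' mutations shared by most cancer cells); all lower-VAF clusters are
#' `subclonal`. The subclonal proportion — the package's intratumor
#' heterogeneity proxy — is the fraction of clustered variants assigned to
#' subclonal clusters. Clusters whose means tie within `merge_tol` were
#' already merged during fitting.
#'
#' @param arch A `vaf_clusters` object.
#' @return The same object with a `label` column on `clusters`,
#'   `subclonal_proportion`, and per-variant labels in `variant_label`.
#' @export
label_clonality <- function(arch) {
  stopifnot(inherits(arch, "vaf_clusters"))
  labels <- c("clonal", rep("subclonal", arch$k - 1L))
  arch$clusters$label <- labels
  arch$labels <- labels
  arch$variant_label <- labels[arch$assignment]
  arch$subclonal_proportion <- sum(arch$clusters$n_variants[-1]) / arch$n
  arch
}

#' Compare intratumor heterogeneity between tumor groups
#'
#' Pools clonal/subclonal variant counts across the labeled tumors of each
#' group and tests the 2x2 (label x group) table with a two-sided Fisher
#' exact test; per-tumor subclonal proportions are reported alongside without
#' a test.
#'
#' @param group_a,group_b Named lists of labeled `vaf_clusters` objects.
#' @param name_a,name_b Group display names.
#' @return An `ith_test` list: `pooled` 2x2 counts, `p_value`, `odds_ratio`,
#'   and `per_tumor` proportions.
#' @export
compare_ith <- function(group_a, group_b, name_a = "group_a", name_b = "group_b") {
  pooled_counts <- function(g) {
    if (length(g) == 0L) abort("zero clustered tumors in a group")
    cl <- sum(map_dbl(g, ~ .x$clusters$n_variants[1]))
    sub <- sum(map_dbl(g, ~ sum(.x$clusters$n_variants[-1])))
    c(clonal = cl, subclonal = sub)
  }
  a <- pooled_counts(group_a); b <- pooled_counts(group_b)
  if (sum(a) == 0 || sum(b) == 0) abort("zero clustered variants in a group")
  m <- rbind(a, b)
  rownames(m) <- c(name_a, name_b)
  ft <- stats::fisher.test(m, alternative = "two.sided")
  tumor_row <- function(fit, smp, grp) {
    tibble(sample = smp, group = grp,
           n_clonal = fit$clusters$n_variants[1],
           n_subclonal = sum(fit$clusters$n_variants[-1]))
  }
  per_tumor <- bind_rows(
    list_rbind(unname(imap(group_a, ~ tumor_row(.x, .y, name_a)))),
    list_rbind(unname(imap(group_b, ~ tumor_row(.x, .y, name_b))))
  ) |>
    mutate(subclonal_proportion = .data$n_subclonal / (.data$n_clonal + .data$n_subclonal))
  structure(list(pooled = m, p_value = ft$p.value, odds_ratio = unname(ft$estimate),
                 subclonal_proportion = setNames(m[, 2] / rowSums(m), rownames(m)),
                 per_tumor = per_tumor),
            class = "ith_test")
}

#' @export
print.ith_test <- function(x, ...) {
  cat("<ith_test> pooled clonal/subclonal counts:\n")
  print(x$pooled)
  cat(sprintf("subclonal proportions: %s\n",
              paste(sprintf("%s = %.3f", names(x$subclonal_proportion),
                            x$subclonal_proportion), collapse = ", ")))
  cat(sprintf("two-sided Fisher p = %.3g\n", x$p_value))
  invisible(x)
}
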