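mk_variants <- function(depth, vaf, chrom = "chr1", pos = seq_along(depth) * 10L) {
  ac <- as.integer(round(depth * vaf))
  tibble::tibble(chrom = chrom, pos = pos, ref = "C", alt = "T", sample = "T1",
                 depth = as.integer(depth), alt_count = ac, vaf = ac / depth,
                 caller_filter = "PASS", gene = "", consequence = "",
                 variant_class = "SNV")
}

# hand-built architecture for label arithmetic checks
mk_arch <- function(means, sizes) {
  k <- length(means)
  structure(list(
    clusters = tibble::tibble(cluster = seq_len(k), mean_vaf = means,
                              weight = sizes / sum(sizes), n_variants = as.integer(sizes)),
    assignment = rep(seq_len(k), sizes), posterior = NULL, k = k,
    loglik = NA_real_, bic = NA_real_, bic_table = NULL, n = sum(sizes),
    merge_tol = 0.02, labels = NULL), class = "vaf_clusters")
}

test_that("pre-clustering filter applies depth, VAF and CNV rules in order", {
  v <- mk_variants(c(99, 200, 150, 150), c(0.4, 0.85, 0.45, 0.45),
                   pos = c(10L, 20L, 55L, 90L))
  cnv <- tibble::tibble(chrom = "chr1", start = 50L, end = 60L)
  out <- filter_for_clustering(v, cnv)
  expect_equal(out$excluded$reason, c("low_depth", "high_vaf", "in_cnv"))
  expect_equal(out$kept$pos, 90L)
  # idempotence
  again <- filter_for_clustering(out$kept, cnv)
  expect_identical(as.data.frame(again$kept), as.data.frame(out$kept))
  # empty input
  e <- filter_for_clustering(empty_variant_table())
  expect_equal(nrow(e$kept), 0L)
})

test_that("a single population is recovered as one cluster near its VAF", {
  withr::with_seed(8L, {
    alt <- rbinom(200L, 150L, 0.5); depth <- rep(150L, 200L)
  })
  fit <- fit_vaf_clusters(alt, depth, seed = 1L)
  expect_equal(fit$k, 1L)
  expect_lt(abs(fit$clusters$mean_vaf - 0.5), 0.02)
})

test_that("two well-separated clusters are recovered with accurate means", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      truth <- rep(c(0.45, 0.15), each = 150L)
      depth <- rpois(300L, 150); alt <- rbinom(300L, depth, truth)
    })
    fit <- fit_vaf_clusters(alt, depth, seed = seed)
    expect_equal(fit$k, 2L)
    expect_lt(abs(fit$clusters$mean_vaf[1] - 0.45), 0.03)
    expect_lt(abs(fit$clusters$mean_vaf[2] - 0.15), 0.03)
  }
})

test_that("clustering is invariant to input order and posteriors are proper", {
  withr::with_seed(5L, {
    truth <- rep(c(0.4, 0.1), each = 100L)
    depth <- rpois(200L, 150); alt <- rbinom(200L, depth, truth)
    perm <- sample.int(200L)
  })
  f1 <- fit_vaf_clusters(alt, depth, seed = 3L)
  f2 <- fit_vaf_clusters(alt[perm], depth[perm], seed = 3L)
  expect_equal(f1$clusters, f2$clusters)
  expect_equal(f1$assignment[perm], f2$assignment)
  expect_equal(rowSums(f1$posterior), rep(1, 200L), tolerance = 1e-9)
})

test_that("too few variants raise the advisory error", {
  expect_error(fit_vaf_clusters(c(40, 42), c(100, 100), seed = 1L), "unclustered")
})

test_that("clonality labeling marks the highest-VAF cluster and computes proportions", {
  a <- label_clonality(mk_arch(c(0.45, 0.12), c(50, 50)))
  expect_equal(a$clusters$label, c("clonal", "subclonal"))
  expect_equal(a$clusters$mean_vaf[a$clusters$label == "clonal"], 0.45)

  single <- label_clonality(mk_arch(0.4, 80))
  expect_equal(single$subclonal_proportion, 0)

  b <- label_clonality(mk_arch(c(0.30, 0.10), c(40, 60)))
  expect_equal(b$subclonal_proportion, 0.6)
})

test_that("pooled heterogeneity comparison matches the enumeration oracle", {
  ga <- list(T1 = label_clonality(mk_arch(c(0.4, 0.1), c(30, 70))))
  gb <- list(T2 = label_clonality(mk_arch(c(0.4, 0.1), c(60, 40))))
  it <- compare_ith(ga, gb, "a", "b")
  expect_equal(it$p_value, oracle_fisher2(rbind(c(30, 70), c(60, 40))), tolerance = 1e-9)
  expect_equal(it$p_value, 3.304593e-05, tolerance = 1e-4)
  expect_equal(unname(it$subclonal_proportion), c(0.7, 0.4))
  # identical pooled tables: p = 1
  same <- compare_ith(ga, list(T2 = label_clonality(mk_arch(c(0.4, 0.1), c(30, 70)))))
  expect_equal(same$p_value, 1)
  # tidy/glance accessors
  expect_equal(nrow(tidy(it)), 2L)
  expect_equal(glance(it)$p_value, it$p_value)
})

test_that("near-identical components merge before labeling", {
  withr::with_seed(2L, {
    depth <- rpois(200L, 150); alt <- rbinom(200L, depth, 0.4)
  })
  fit <- fit_vaf_clusters(alt, depth, k_max = 3L, seed = 2L, merge_tol = 0.05)
  expect_true(all(abs(diff(fit$clusters$mean_vaf)) >= 0.05 | fit$k == 1L))
})
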