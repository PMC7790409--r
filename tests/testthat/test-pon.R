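mk_calls <- function(smp, pos, filter = "PASS") {
  tibble::tibble(chrom = "chr1", pos = as.integer(pos), ref = "C", alt = "T",
                 sample = smp, depth = 100L, alt_count = 40L, vaf = 0.4,
                 caller_filter = rep_len(filter, length(pos)),
                 gene = "", consequence = "", variant_class = "SNV")
}

test_that("set1 is the intersection of the two healthy call sets", {
  hg <- mk_calls("healthy", c(10, 20))
  hs <- mk_calls("healthy", c(20, 30))
  tumors <- list(T1 = mk_calls("T1", 999), T2 = mk_calls("T2", 998), T3 = mk_calls("T3", 997))
  pon <- build_pon(hg, hs, tumors, filter_config(n_all = 3, n_most = 3, max_no_pass_set2 = 1))
  expect_equal(pon$pos, 20L)
  expect_equal(pon$provenance, "set1")
})

test_that("set2 tolerates NO_PASS in at most the configured number of samples", {
  hg <- mk_calls("healthy", 50)
  hs <- mk_calls("healthy", integer())
  cfg <- filter_config(n_all = 3, n_most = 3, max_no_pass_set2 = 1)
  tum <- function(f1, f2, f3) list(
    T1 = mk_calls("T1", 50, f1), T2 = mk_calls("T2", 50, f2), T3 = mk_calls("T3", 50, f3))
  pon1 <- build_pon(hg, hs, tum("NO_PASS", "PASS", "PASS"), cfg)
  expect_true(pon1$set2[pon1$pos == 50])
  pon2 <- build_pon(hg, hs, tum("NO_PASS", "NO_PASS", "PASS"), cfg)
  expect_false(any(pon2$set2))
})

test_that("set3 requires PASS in every sample where called", {
  hg <- mk_calls("healthy", 60)
  hs <- mk_calls("healthy", integer())
  cfg <- filter_config(n_all = 3, n_most = 3, max_no_pass_set2 = 1)
  all_pass <- list(T1 = mk_calls("T1", 60), T2 = mk_calls("T2", 60), T3 = mk_calls("T3", 60))
  pon <- build_pon(hg, hs, all_pass, cfg)
  expect_true(pon$set3[pon$pos == 60])
  one_np <- list(T1 = mk_calls("T1", 60, "NO_PASS"), T2 = mk_calls("T2", 60), T3 = mk_calls("T3", 60))
  pon2 <- build_pon(hg, hs, one_np, cfg)
  expect_false(any(pon2$set3))
  expect_true(any(pon2$set2))  # still eligible for set2 under max_no_pass 1
})

test_that("sample-count mismatch errors unless overridden", {
  hg <- mk_calls("healthy", 1); hs <- mk_calls("healthy", 1)
  tumors <- list(T1 = mk_calls("T1", 2))
  expect_error(build_pon(hg, hs, tumors, filter_config(n_all = 3, n_most = 2)), "n_all")
  expect_silent(build_pon(hg, hs, tumors, filter_config(n_all = 3, n_most = 2),
                          allow_n_mismatch = TRUE))
})

test_that("removal reasons follow the fixed precedence and known sites remove variants", {
  hg <- mk_calls("healthy", c(10, 20))
  hs <- mk_calls("healthy", c(10, 20))
  tumors <- mk_calls("T1", c(10, 20, 30, 40))
  pon <- tibble::tibble(chrom = "chr1", pos = 10L, ref = "C", alt = "T")
  known <- tibble::tibble(chrom = "chr1", pos = c(30L), ref = "C", alt = "T")
  out <- filter_somatic(tumors, pon, list(hg, hs), list(dbsnp = known))
  # 10 hits pon before healthy; 20 healthy; 30 known; 40 retained
  rep <- setNames(out$report$n, out$report$reason)
  expect_equal(rep[["pon"]], 1L)
  expect_equal(rep[["healthy"]], 1L)
  expect_equal(rep[["known_sites"]], 1L)
  expect_equal(out$variants$pos, 40L)
})

test_that("PON + filter agree exactly with the brute-force oracle on random toy cohorts", {
  for (seed in 1:20) {
    n_samp <- 2L + (seed %% 5L)
    co <- random_toy_cohort(n_samp, 80L + 10L * (seed %% 4L), seed)
    cfg <- filter_config(n_all = n_samp, n_most = max(n_samp - 1L, 1L), max_no_pass_set2 = 1L)
    pon <- build_pon(co$healthy_germline, co$healthy_somatic, co$tumors, cfg)
    out <- filter_somatic(dplyr::bind_rows(co$tumors), pon,
                          list(co$healthy_germline, co$healthy_somatic),
                          list(known = co$known_sites))
    oracle <- oracle_pon_filter(co, n_all = cfg$n_all, n_most = cfg$n_most,
                                max_no_pass = cfg$max_no_pass_set2)
    expect_identical(sort(variant_key(pon)), oracle$pon)
    o <- dplyr::arrange(oracle$kept, chrom, pos, sample, ref, alt)
    expect_identical(as.data.frame(out$variants), as.data.frame(o))
  }
})

test_that("enlarging a known-site list never grows the retained set", {
  co <- random_toy_cohort(4L, 120L, 99L)
  cfg <- filter_config(n_all = 4L, n_most = 3L, max_no_pass_set2 = 1L)
  pon <- build_pon(co$healthy_germline, co$healthy_somatic, co$tumors, cfg)
  healthy <- list(co$healthy_germline, co$healthy_somatic)
  base <- filter_somatic(dplyr::bind_rows(co$tumors), pon, healthy, list(k = co$known_sites))
  bigger <- dplyr::bind_rows(co$known_sites,
                             dplyr::slice_head(base$variants, n = 10) |>
                               dplyr::select(chrom, pos, ref, alt))
  out2 <- filter_somatic(dplyr::bind_rows(co$tumors), pon, healthy, list(k = bigger))
  expect_true(all(variant_key(out2$variants) %in% variant_key(base$variants)))
  expect_lte(nrow(out2$variants), nrow(base$variants))
})

test_that("every PON entry carries non-empty provenance and the union covers all entries", {
  co <- random_toy_cohort(5L, 150L, 7L)
  pon <- build_pon(co$healthy_germline, co$healthy_somatic, co$tumors,
                   filter_config(n_all = 5L, n_most = 4L, max_no_pass_set2 = 1L))
  expect_true(all(nzchar(pon$provenance)))
  expect_equal(sum(pon$set1 | pon$set2 | pon$set3), nrow(pon))
})
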