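test_that("substitutions classify by transition/transversion and base class", {
  expect_equal(classify_substitution("C", "T"),
               tibble::tibble(type = "Ts", base_class = "CG"))
  expect_equal(classify_substitution("G", "A"),
               tibble::tibble(type = "Ts", base_class = "CG"))
  expect_equal(classify_substitution(c("C", "A"), c("A", "G")),
               tibble::tibble(type = c("Tv", "Ts"), base_class = c("CG", "AT")))
  expect_error(classify_substitution("C", "C"), "ref == alt")
  expect_error(classify_substitution("N", "A"), "A/C/G/T")
})

test_that("hotspot calls follow the WRC/GYW motif with edge handling", {
  ts <- make_targets(c(chr1 = "TACGA"))
  expect_true(is_hotspot(ts, "chr1", 3L, "C"))     # context TAC: W=T, R=A
  expect_false(as.logical(is_hotspot(ts, "chr1", 4L, "G")))  # GA. needs Y at +1; A fails
  ts2 <- make_targets(c(chr1 = "AGTAG"))
  h <- is_hotspot(ts2, "chr1", 5L, "G")            # no downstream context
  expect_false(as.logical(h))
  expect_true(attr(h, "edge")[1])
  expect_error(is_hotspot(ts, "chr1", 3L, "G"), "ref mismatch")
})

test_that("target composition counts bases and hotspot C/G exactly", {
  ts <- make_targets(c(chr1 = "TACGT"))
  comp <- target_composition(ts)
  expect_equal(comp$n_cg, 2L)
  expect_equal(comp$n_at, 3L)
  expect_equal(comp$n_cg_hotspot, 1L)  # the C in TAC; the G at 4 is edge-limited
})

test_that("hotspot scan matches the regex oracle and is strand-symmetric", {
  for (seed in 1:20) {
    s <- random_dna(1000L, seed)
    ts <- make_targets(c(chr1 = s))
    st <- target_sites(ts)
    got <- sort(st$pos[st$hotspot])
    expect_identical(got, oracle_hotspot_positions(s))
    # reverse complement, re-index: hotspot status preserved
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    ts_rc <- make_targets(c(chr1 = rc))
    st_rc <- target_sites(ts_rc)
    expect_identical(sort(1001L - st_rc$pos[st_rc$hotspot]), got)
  }
})

test_that("the 4-mer motif variant and a custom R alphabet are honored", {
  # WRCY needs a pyrimidine after the C: TACT qualifies, TACA does not
  ts <- make_targets(c(chr1 = "TACTG", chr2 = "TACAG"))
  expect_true(is_hotspot(ts, "chr1", 3L, "C", motif = "wrcy"))
  expect_false(as.logical(is_hotspot(ts, "chr2", 3L, "C", motif = "wrcy")))
  # printed-variant alphabet R = C/G: TAC no longer matches, TCC does
  ts3 <- make_targets(c(chr1 = "TCCGA"))
  expect_true(is_hotspot(ts3, "chr1", 3L, "C", r_bases = c("C", "G")))
  expect_false(as.logical(is_hotspot(make_targets(c(chr1 = "TACGA")),
                                     "chr1", 3L, "C", r_bases = c("C", "G"))))
})

test_that("spectrum frequencies normalize by the right denominators", {
  s <- random_dna(2000L, 42L)
  ts <- make_targets(c(chr1 = s))
  comp <- target_composition(ts)
  st <- target_sites(ts)
  cg <- st[st$base %in% c("C", "G"), ][1:4, ]
  v <- tibble::tibble(chrom = "chr1", pos = cg$pos, ref = cg$base,
                      alt = ifelse(cg$base == "C", "T", "A"),
                      sample = "S1", depth = 100L, alt_count = 40L, vaf = 0.4,
                      caller_filter = "PASS", gene = "", consequence = "",
                      variant_class = "SNV")
  spec <- spectrum_summary(v, ts, c(S1 = "g1"), comp)
  expect_equal(spec$per_sample$n_ts_cg, 4L)
  expect_equal(spec$per_sample$freq_ts_cg, 4 / comp$n_cg)
  expect_equal(spec$per_sample$n_ts_cg_hotspot, sum(cg$hotspot))
  # doubling counts and denominators leaves frequencies unchanged
  spec2 <- spectrum_summary(dplyr::mutate(dplyr::bind_rows(v, dplyr::mutate(v, sample = "S2")),),
                            ts, c(S1 = "g1", S2 = "g1"), comp)
  expect_equal(spec2$per_group$n_ts_cg, 8L)
})

test_that("zero variants give an all-zero summary", {
  ts <- make_targets(c(chr1 = random_dna(500L, 2L)))
  spec <- spectrum_summary(empty_variant_table(), ts, c(S1 = "g1"))
  expect_equal(spec$per_sample$n_ts_cg, 0L)
  expect_equal(spec$per_sample$freq_ts_cg_hotspot, 0)
})

test_that("group comparisons match exact-test oracles", {
  # identical margins: Fisher p = 1
  expect_equal(oracle_fisher2(rbind(c(10, 90), c(10, 90))), 1)
  expect_equal(stats::fisher.test(rbind(c(10, 90), c(10, 90)))$p.value, 1)
  # frozen enumeration value for the asymmetric table
  m <- rbind(c(1, 9), c(11, 3))
  expect_equal(oracle_fisher2(m), 0.002759456, tolerance = 1e-6)
  expect_equal(stats::fisher.test(m)$p.value, oracle_fisher2(m), tolerance = 1e-9)
  # Pearson statistic equals the closed form
  m2 <- rbind(c(20, 980), c(40, 960))
  expect_equal(unname(suppressWarnings(stats::chisq.test(m2, correct = FALSE))$statistic),
               oracle_pearson(m2), tolerance = 1e-12)
})

test_that("compare_spectra builds the declared contrasts on pooled counts", {
  s <- random_dna(5000L, 31L)
  ts <- make_targets(c(chr1 = s))
  st <- target_sites(ts)
  comp <- target_composition(ts)
  pick <- function(n, smp) {
    cg <- st[st$base %in% c("C", "G"), ]
    k <- cg[seq_len(n), ]
    tibble::tibble(chrom = "chr1", pos = k$pos, ref = k$base,
                   alt = ifelse(k$base == "C", "T", "A"), sample = smp,
                   depth = 100L, alt_count = 40L, vaf = 0.4, caller_filter = "PASS",
                   gene = "", consequence = "", variant_class = "SNV")
  }
  v <- dplyr::bind_rows(pick(30, "A1"), pick(10, "B1"))
  spec <- spectrum_summary(v, ts, c(A1 = "ga", B1 = "gb"), comp)
  res <- compare_spectra(spec, "ga", "gb", mode = "fisher")
  expect_equal(nrow(res), 4L)
  tot <- res[res$contrast == "total_cg_between_groups", ]
  expect_equal(tot$x11, 30); expect_equal(tot$x21, 10)
  expect_equal(tot$x12, comp$n_cg - 30)
  # p-value equals the enumeration oracle on the same table
  expect_equal(tot$p_value,
               oracle_fisher2(rbind(c(tot$x11, tot$x12), c(tot$x21, tot$x22))),
               tolerance = 1e-9)
  chi <- compare_spectra(spec, "ga", "gb", mode = "chi2")
  m <- rbind(c(chi$x11[1], chi$x12[1]), c(chi$x21[1], chi$x22[1]))
  expect_equal(chi$statistic[1], oracle_pearson(m), tolerance = 1e-9)
})
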