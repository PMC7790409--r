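write_set <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

mk_gene_variants <- function(smp, genes, consequences) {
  tibble::tibble(chrom = "chr1", pos = seq_along(genes) * 100L, ref = "C", alt = "T",
                 sample = smp, depth = 100L, alt_count = 40L, vaf = 0.4,
                 caller_filter = "PASS", gene = genes, consequence = consequences,
                 variant_class = "SNV")
}

test_that("gene sets load normalized, deduplicated, with union", {
  d <- write_set(c("Fas", "FAS", "Myc", "# comment", "", "Pim1"))
  l <- write_set(c("Bcl2", "Myc"))
  sets <- load_gene_sets(d, l)
  expect_equal(sets$drivers, c("FAS", "MYC", "PIM1"))
  expect_equal(sets$lymphoma, c("BCL2", "MYC"))
  expect_equal(sets$union, c("BCL2", "FAS", "MYC", "PIM1"))
  expect_error(load_gene_sets(write_set("# only a comment"), l), "empty")
})

test_that("matrix restricts to the union and reduces to the most severe consequence", {
  sets <- load_gene_sets(write_set(c("X")), write_set(c("Z")))
  v <- dplyr::bind_rows(
    mk_gene_variants("T1", c("X", "Y"), c("missense", "synonymous")),
    mk_gene_variants("T2", c("X", "X"), c("synonymous", "frameshift"))
  )
  gm <- annotate_cancer_genes(v, sets)
  expect_setequal(unique(gm$cells$gene), "X")
  t2 <- gm$cells[gm$cells$sample == "T2", ]
  expect_equal(t2$consequence, "frameshift")
  expect_equal(t2$n_variants, 2L)
  expect_error(annotate_cancer_genes(
    mk_gene_variants("T1", "X", "weird_consequence"), sets), "weird_consequence")
})

test_that("matrix equals hand enumeration on a toy cohort and severity is order-independent", {
  sets <- load_gene_sets(write_set(c("G1", "G2", "G3")), write_set(c("G4", "G5")))
  v <- dplyr::bind_rows(
    mk_gene_variants("T1", c("G1", "G2", "G2"), c("missense", "synonymous", "stop_gained")),
    mk_gene_variants("T2", c("G4"), c("utr")),
    mk_gene_variants("T3", c("G1", "G5"), c("frameshift", "splice"))
  )
  gm <- annotate_cancer_genes(v, sets)
  expected <- tibble::tibble(
    gene = c("G1", "G1", "G2", "G4", "G5"),
    sample = c("T1", "T3", "T1", "T2", "T3"),
    n_variants = c(1L, 1L, 2L, 1L, 1L),
    consequence = c("missense", "frameshift", "stop_gained", "utr", "splice")
  )
  expect_equal(as.data.frame(gm$cells), as.data.frame(expected))
  # column sums against independent per-tumor counts
  per_tumor <- table(unique(v[v$gene %in% sets$union, c("gene", "sample")])$sample)
  cell_sums <- table(gm$cells$sample)
  expect_equal(as.integer(cell_sums[names(per_tumor)]), as.integer(per_tumor))
  # shuffling variant rows leaves the reduction unchanged
  withr::with_seed(4L, v2 <- v[sample.int(nrow(v)), ])
  expect_equal(annotate_cancer_genes(v2, sets)$cells, gm$cells)
})

test_that("exclusive/shared genes partition correctly with recurrence filtering", {
  sets <- load_gene_sets(write_set(c("P", "Q", "R", "S")), write_set("Q"))
  ma <- annotate_cancer_genes(dplyr::bind_rows(
    mk_gene_variants("A1", c("P", "Q"), c("missense", "missense")),
    mk_gene_variants("A2", c("P", "R"), c("missense", "missense"))), sets)
  mb <- annotate_cancer_genes(dplyr::bind_rows(
    mk_gene_variants("B1", c("Q", "S"), c("missense", "missense")),
    mk_gene_variants("B2", c("S"), "missense")), sets)
  ex <- exclusive_genes(ma, mb)
  expect_equal(ex$exclusive_a, c("P", "R"))
  expect_equal(ex$exclusive_b, "S")
  expect_equal(ex$shared, "Q")
  # partition property
  expect_length(intersect(ex$exclusive_a, ex$shared), 0L)
  expect_setequal(c(ex$exclusive_a, ex$exclusive_b, ex$shared), c("P", "Q", "R", "S"))
  # min-recurrence 2 drops single-tumor genes entirely
  ex2 <- exclusive_genes(ma, mb, min_recurrence = 2L)
  expect_equal(ex2$exclusive_a, "P")
  expect_equal(ex2$exclusive_b, "S")
  expect_length(ex2$shared, 0L)
  # identical matrices: nothing exclusive
  ex3 <- exclusive_genes(ma, ma)
  expect_length(ex3$exclusive_a, 0L)
  expect_length(ex3$exclusive_b, 0L)
})

test_that("exclusive-gene spectrum proportions and degenerate cases behave", {
  s <- random_dna(3000L, 17L)
  ts <- make_targets(c(chr1 = s))
  st <- target_sites(ts)
  cg <- st[st$base %in% c("C", "G"), ]
  at <- st[st$base %in% c("A", "T"), ]
  v <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = cg$pos[1:18], ref = cg$base[1:18],
                   alt = ifelse(cg$base[1:18] == "C", "T", "A")),
    tibble::tibble(chrom = "chr1", pos = at$pos[1:2], ref = at$base[1:2],
                   alt = ifelse(at$base[1:2] == "A", "G", "C"))
  ) |>
    dplyr::mutate(sample = "T1", depth = 100L, alt_count = 40L, vaf = 0.4,
                  caller_filter = "PASS", gene = "X", consequence = "missense",
                  variant_class = "SNV")
  res <- exclusive_spectrum(v, ts)
  expect_equal(res$proportion[res$split == "cg_vs_at"], 0.9)
  # all-hotspot degenerate case
  hot <- cg[cg$hotspot, ][1:5, ]
  vh <- tibble::tibble(chrom = "chr1", pos = hot$pos, ref = hot$base,
                       alt = ifelse(hot$base == "C", "T", "A"), sample = "T1",
                       depth = 100L, alt_count = 40L, vaf = 0.4, caller_filter = "PASS",
                       gene = "X", consequence = "missense", variant_class = "SNV")
  res_h <- exclusive_spectrum(vh, ts)
  expect_equal(res_h$proportion[res_h$split == "hotspot_vs_nonhotspot"], 1.0)
  # zero SNVs: NA tests, no error
  res_0 <- exclusive_spectrum(empty_variant_table(), ts)
  expect_true(all(is.na(res_0$p_value) | res_0$p_value >= 0))
  expect_true(all(is.na(res_0$proportion)))
})
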