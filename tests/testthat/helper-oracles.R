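# Independent oracles and small fixture builders. Each oracle is a
# brute-force or closed-form computation that shares no code with the
# implementation it checks.

# Build a target_space by writing FASTA/BED to disk and loading through the
# public reader, so fixtures exercise the I/O path too.
make_targets <- function(seqs, bed = NULL) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(purrr::imap(seqs, ~ c(paste0(">", .y), .x))), fa)
  bedf <- tempfile(fileext = ".bed")
  if (is.null(bed)) {
    bed <- tibble::tibble(chrom = names(seqs), start = 0L, end = nchar(unname(seqs)))
  }
  readr::write_tsv(bed, bedf, col_names = FALSE)
  load_targets(bedf, fa)
}

# Write a minimal VCF by hand (independent of write_variants_vcf).
write_raw_vcf <- function(path, rows, contig = "chr1", contig_len = 1000L,
                          sample = "S1") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  writeLines(c(hdr, rows), path)
  path
}

# Regex-based both-strand hotspot oracle: WRC with the C mutable (match ends
# at the C) and GYW with the G mutable (match starts at the G), via
# lookahead so overlapping motifs are all found.
oracle_hotspot_positions <- function(seq, motif = "wrc") {
  fwd <- if (motif == "wrc") "(?=[AT][AG]C)" else "(?=[AT][AG]C[CT])"
  rev <- if (motif == "wrc") "(?=G[CT][AT])" else "(?=[AG]G[CT][AT])"
  starts_f <- gregexpr(fwd, seq, perl = TRUE)[[1]]
  starts_r <- gregexpr(rev, seq, perl = TRUE)[[1]]
  c_pos <- if (starts_f[1] == -1) integer() else as.integer(starts_f) + 2L
  g_pos <- if (starts_r[1] == -1) integer() else
    as.integer(starts_r) + (if (motif == "wrc") 0L else 1L)
  sort(unique(c(c_pos, g_pos)))
}

# Exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities over all tables with the same margins that are no more
# probable than the observed one.
oracle_fisher2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  obs <- dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Closed-form Pearson chi-square statistic.
oracle_pearson <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Random toy cohort for PON/filter oracle tests: random variant keys with
# random PASS/NO_PASS labels spread over healthy and tumor samples.
random_toy_cohort <- function(n_samples, n_keys, seed) {
  withr::with_seed(seed, {
    keys <- tibble::tibble(
      chrom = "chr1",
      pos = sample.int(5000L, n_keys),
      ref = sample(c("A", "C", "G", "T"), n_keys, replace = TRUE),
      alt = NA_character_
    )
    keys$alt <- purrr::map_chr(keys$ref, ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1))
    samples <- sprintf("T%d", seq_len(n_samples))
    mk_calls <- function(smp, p_present = 0.5) {
      sel <- runif(n_keys) < p_present
      k <- keys[sel, , drop = FALSE]
      tibble::tibble(
        chrom = k$chrom, pos = k$pos, ref = k$ref, alt = k$alt, sample = smp,
        depth = 100L, alt_count = 40L, vaf = 0.4,
        caller_filter = sample(c("PASS", "NO_PASS"), nrow(k), replace = TRUE, prob = c(0.8, 0.2)),
        gene = "", consequence = "",
        variant_class = ifelse(nchar(k$ref) == 1 & nchar(k$alt) == 1, "SNV", "INDEL")
      )
    }
    list(
      healthy_germline = mk_calls("healthy", 0.6),
      healthy_somatic = mk_calls("healthy", 0.6),
      tumors = purrr::map(setNames(samples, samples), mk_calls),
      known_sites = keys[runif(n_keys) < 0.15, , drop = FALSE]
    )
  })
}

# Brute-force PON + filter oracle: explicit loops over keys and samples,
# evaluating each rule by direct set membership.
oracle_pon_filter <- function(cohort, n_all, n_most, max_no_pass) {
  key_of <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  kg <- unique(key_of(cohort$healthy_germline))
  ks <- unique(key_of(cohort$healthy_somatic))
  healthy_any <- union(kg, ks)
  tum_keys <- lapply(cohort$tumors, key_of)
  tum_filt <- lapply(cohort$tumors, function(t) setNames(t$caller_filter, key_of(t)))
  all_keys <- unique(c(healthy_any, unlist(tum_keys)))
  pon <- character()
  for (k in all_keys) {
    in_set1 <- (k %in% kg) && (k %in% ks)
    called <- vapply(tum_keys, function(tk) k %in% tk, logical(1))
    n_called <- sum(called)
    n_np <- 0L
    for (s in names(tum_keys)) {
      if (k %in% tum_keys[[s]] && tum_filt[[s]][[k]] == "NO_PASS") n_np <- n_np + 1L
    }
    in_set2 <- (k %in% healthy_any) && n_called == n_all && n_np <= max_no_pass
    in_set3 <- (k %in% healthy_any) && n_called >= n_most && n_np == 0L
    if (in_set1 || in_set2 || in_set3) pon <- c(pon, k)
  }
  known <- paste(cohort$known_sites$chrom, cohort$known_sites$pos,
                 cohort$known_sites$ref, cohort$known_sites$alt, sep = ":")
  kept <- lapply(cohort$tumors, function(t) {
    kk <- key_of(t)
    t[!(kk %in% pon) & !(kk %in% healthy_any) & !(kk %in% known), , drop = FALSE]
  })
  list(pon = sort(pon), kept = dplyr::bind_rows(kept))
}

# Compact simulated cohorts for pipeline-level tests.
small_sim_config <- function(seed = 1L, n_wt = 2L, n_ki = 2L,
                             mut_wt = 120L, mut_ki = 200L,
                             genome_length = 40000L, ...) {
  sim_config(
    genome_length = genome_length,
    groups = list(
      wt_like = utils::modifyList(group_preset("wt_like"),
                                  list(n_tumors = n_wt, mutations_per_tumor = mut_wt)),
      ki_like = utils::modifyList(group_preset("ki_like"),
                                  list(n_tumors = n_ki, mutations_per_tumor = mut_ki))
    ),
    n_germline = 30L, seed = seed, ...
  )
}

random_dna <- function(n, seed, gc = 0.42) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                               collapse = ""))
}
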