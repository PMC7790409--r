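#' Classify a substitution by type and reference base class
#'
#' Transitions are purine<->purine or pyrimidine<->pyrimidine changes
#' (`A<->G`, `C<->T`); everything else is a transversion. The base class is
#' taken from the reference allele: `CG` for C/G, `AT` for A/T. In
#' UNG-deficient B cells the replication of unrepaired AID-generated U:G
#' mismatches yields specifically transitions at C/G, so this split carries
#' the biology.
#'
#' @param ref,alt Single reference / alternate bases (vectorized).
#' @return Tibble with `type` (`Ts`/`Tv`) and `base_class` (`CG`/`AT`).
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) abort("classify_substitution: alleles must be single A/C/G/T bases")
  if (any(ref == alt)) abort("classify_substitution: ref == alt")
  ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
        (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  tibble(type = ifelse(ts, "Ts", "Tv"),
         base_class = ifelse(ref %in% c("C", "G"), "CG", "AT"))
}

motif_sets <- function(r_bases = c("A", "G"), y_bases = c("C", "T"), w_bases = c("A", "T")) {
  list(W = toupper(w_bases), R = toupper(r_bases), Y = toupper(y_bases))
}

# Per-chromosome hotspot scan. Returns logical vectors over every position of
# the chromosome: is the base a hotspot C/G, and is its motif context truncated
# by the chromosome end. Motif "wrc" is the 3-mer WRC/GYW (mutated base C/G);
# "wrcy" the 4-mer WRCY/RGYW.
scan_chrom_hotspots <- function(chars, motif = c("wrc", "wrcy"), sets = motif_sets()) {
  motif <- match.arg(motif)
  n <- length(chars)
  at <- function(off) {
    # base at position p + off, NA outside the chromosome
    idx <- seq_len(n) + off
    out <- rep(NA_character_, n)
    keep <- idx >= 1L & idx <= n
    out[keep] <- chars[idx[keep]]
    out
  }
  inset <- function(x, set) !is.na(x) & x %in% set
  isC <- chars == "C"; isG <- chars == "G"
  if (motif == "wrc") {
    hotC <- isC & inset(at(-2L), sets$W) & inset(at(-1L), sets$R)
    hotG <- isG & inset(at(+1L), sets$Y) & inset(at(+2L), sets$W)
    edgeC <- isC & (is.na(at(-2L)) | is.na(at(-1L)))
    edgeG <- isG & (is.na(at(+1L)) | is.na(at(+2L)))
  } else {
    hotC <- isC & inset(at(-2L), sets$W) & inset(at(-1L), sets$R) & inset(at(+1L), sets$Y)
    hotG <- isG & inset(at(-1L), sets$R) & inset(at(+1L), sets$Y) & inset(at(+2L), sets$W)
    edgeC <- isC & (is.na(at(-2L)) | is.na(at(-1L)) | is.na(at(+1L)))
    edgeG <- isG & (is.na(at(-1L)) | is.na(at(+1L)) | is.na(at(+2L)))
  }
  list(hotspot = hotC | hotG, edge = edgeC | edgeG)
}

#' Enumerate target-space sites with base and hotspot annotation
#'
#' One row per targeted base. Hotspot context is read from the full reference
#' chromosome (available beyond a capture boundary); positions whose context
#' runs past the chromosome end are flagged `edge` and never hotspot.
#'
#' @param targets A `target_space`.
#' @param motif `"wrc"` (3-mer WRC/GYW, default) or `"wrcy"` (4-mer
#'   WRCY/RGYW).
#' @param r_bases,y_bases,w_bases IUPAC degeneracy sets; defaults are the
#'   standard R = A/G, Y = C/T, W = A/T.
#' @return Tibble with `chrom`, `pos` (1-based), `base`, `hotspot`, `edge`.
#' @export
target_sites <- function(targets, motif = "wrc",
                         r_bases = c("A", "G"), y_bases = c("C", "T"),
                         w_bases = c("A", "T")) {
  sets <- motif_sets(r_bases, y_bases, w_bases)
  map_dfr(unique(targets$intervals$chrom), function(ch) {
    chars <- strsplit(as.character(targets$seqs[[ch]]), "", fixed = TRUE)[[1]]
    scan <- scan_chrom_hotspots(chars, motif, sets)
    ivs <- filter(targets$intervals, .data$chrom == ch)
    pos <- unlist(map2(ivs$start, ivs$end, function(s, e) seq.int(s + 1L, e)))
    tibble(chrom = ch, pos = as.integer(pos), base = chars[pos],
           hotspot = scan$hotspot[pos], edge = scan$edge[pos])
  })
}

#' Is a reference C/G in AID hotspot context?
#'
#' A C at position p is a hotspot when the two upstream reference bases match
#' W,R; a G when the two downstream bases match Y,W (the reverse-complement
#' reading of the same motif). Status depends only on the reference sequence.
#'
#' @param targets A `target_space`.
#' @param chrom,pos,ref Vectors describing the queried sites; `ref` must match
#'   the reference base (checked).
#' @inheritParams target_sites
#' @return Logical vector; positions with chromosome-edge-truncated context
#'   are `FALSE` and marked in the `"edge"` attribute.
#' @export
is_hotspot <- function(targets, chrom, pos, ref, motif = "wrc",
                       r_bases = c("A", "G"), y_bases = c("C", "T"),
                       w_bases = c("A", "T")) {
  sets <- motif_sets(r_bases, y_bases, w_bases)
  out <- logical(length(pos)); edge <- logical(length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    chars <- strsplit(as.character(targets$seqs[[ch]]), "", fixed = TRUE)[[1]]
    p <- as.integer(pos[sel])
    bad <- chars[p] != toupper(ref[sel])
    if (any(bad)) {
      i <- sel[which(bad)[1]]
      abort(sprintf("ref mismatch at %s:%d: expected %s, reference has %s",
                    ch, pos[i], ref[i], chars[pos[i]]))
    }
    scan <- scan_chrom_hotspots(chars, motif, sets)
    out[sel] <- scan$hotspot[p]
    edge[sel] <- scan$edge[p]
  }
  attr(out, "edge") <- edge
  out
}

#' Base-composition denominators of the target space
#'
#' Counts the mutation-eligible bases the per-base frequencies in the spectrum
#' summary are normalized by: all C/G bases, the C/G bases in hotspot context,
#' and all A/T bases. Edge positions count toward `n_cg` but never toward
#' `n_cg_hotspot`.
#'
#' @inheritParams target_sites
#' @return One-row tibble with `n_cg`, `n_cg_hotspot`, `n_at`.
#' @export
target_composition <- function(targets, motif = "wrc",
                               r_bases = c("A", "G"), y_bases = c("C", "T"),
                               w_bases = c("A", "T")) {
  st <- target_sites(targets, motif, r_bases, y_bases, w_bases)
  tibble(
    n_cg = sum(st$base %in% c("C", "G")),
    n_cg_hotspot = sum(st$hotspot),
    n_at = sum(st$base %in% c("A", "T"))
  )
}

spectrum_count_cols <- c("n_ts_cg", "n_tv_cg", "n_ts_at", "n_tv_at",
                         "n_ts_cg_hotspot", "n_tv_cg_hotspot")

#' Per-sample and per-group mutation-spectrum summary
#'
#' Classifies every filtered SNV by substitution type, base class and hotspot
#' context and normalizes counts by the target-space denominators. Group-level
#' frequencies are reported two ways: pooled (summed counts over the shared
#' denominator — the headline figure, since the chi-square comparison operates
#' on pooled counts) and as the mean of per-sample frequencies.
#'
#' @param variants Filtered variant table (SNVs are used; others ignored).
#' @param targets A `target_space` (for hotspot context).
#' @param grouping Tibble with `sample`, `group` columns, or a named character
#'   vector `sample -> group`.
#' @param composition Optional precomputed [target_composition()].
#' @inheritParams target_sites
#' @return A `spectrum_summary` object: list with `per_sample`, `per_group`,
#'   `composition`, and `n_outside_targets`.
#' @export
spectrum_summary <- function(variants, targets, grouping, composition = NULL,
                             motif = "wrc", r_bases = c("A", "G"),
                             y_bases = c("C", "T"), w_bases = c("A", "T")) {
  if (is.character(grouping)) grouping <- tibble(sample = names(grouping), group = unname(grouping))
  composition <- composition %||% target_composition(targets, motif, r_bases, y_bases, w_bases)

  snv <- filter(variants, .data$variant_class == "SNV")
  inside <- rep(FALSE, nrow(snv))
  for (i in seq_len(nrow(targets$intervals))) {
    iv <- targets$intervals[i, ]
    inside <- inside | (snv$chrom == iv$chrom & snv$pos > iv$start & snv$pos <= iv$end)
  }
  n_outside <- sum(!inside)
  snv <- snv[inside, , drop = FALSE]

  if (nrow(snv) > 0L) {
    cls <- classify_substitution(snv$ref, snv$alt)
    snv$type <- cls$type; snv$base_class <- cls$base_class
    snv$hotspot <- as.logical(is_hotspot(targets, snv$chrom, snv$pos, snv$ref,
                                         motif, r_bases, y_bases, w_bases))
  } else {
    snv$type <- character(); snv$base_class <- character(); snv$hotspot <- logical()
  }

  per_sample <- snv |>
    group_by(.data$sample) |>
    summarise(
      n_ts_cg = sum(.data$type == "Ts" & .data$base_class == "CG"),
      n_tv_cg = sum(.data$type == "Tv" & .data$base_class == "CG"),
      n_ts_at = sum(.data$type == "Ts" & .data$base_class == "AT"),
      n_tv_at = sum(.data$type == "Tv" & .data$base_class == "AT"),
      n_ts_cg_hotspot = sum(.data$type == "Ts" & .data$base_class == "CG" & .data$hotspot),
      n_tv_cg_hotspot = sum(.data$type == "Tv" & .data$base_class == "CG" & .data$hotspot),
      .groups = "drop"
    ) |>
    right_join(grouping, by = "sample") |>
    mutate(across(all_of(spectrum_count_cols), ~ tidyr::replace_na(.x, 0L))) |>
    add_spectrum_freqs(composition) |>
    arrange(.data$sample) |>
    select("sample", "group", everything())

  per_group <- per_sample |>
    group_by(.data$group) |>
    summarise(
      n_samples = n(),
      across(all_of(spectrum_count_cols), sum),
      mean_freq_ts_cg = mean(.data$freq_ts_cg),
      mean_freq_ts_cg_hotspot = mean(.data$freq_ts_cg_hotspot),
      .groups = "drop"
    ) |>
    add_spectrum_freqs(composition)

  structure(list(per_sample = per_sample, per_group = per_group,
                 composition = composition, n_outside_targets = n_outside),
            class = "spectrum_summary")
}

add_spectrum_freqs <- function(x, comp) {
  mutate(x,
    freq_ts_cg = .data$n_ts_cg / comp$n_cg,
    freq_tv_cg = .data$n_tv_cg / comp$n_cg,
    freq_ts_at = .data$n_ts_at / comp$n_at,
    freq_tv_at = .data$n_tv_at / comp$n_at,
    freq_ts_cg_hotspot = .data$n_ts_cg_hotspot / comp$n_cg_hotspot,
    freq_ts_cg_nonhotspot = (.data$n_ts_cg - .data$n_ts_cg_hotspot) /
      (comp$n_cg - comp$n_cg_hotspot),
    enrichment_ratio = .data$freq_ts_cg_hotspot / .data$freq_ts_cg_nonhotspot
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("<spectrum_summary>\n")
  print(x$per_group)
  if (x$n_outside_targets > 0L)
    cat(sprintf("(%d SNV(s) outside targets excluded)\n", x$n_outside_targets))
  invisible(x)
}

two_by_two_test <- function(m, mode = c("chi2", "fisher")) {
  mode <- match.arg(mode)
  if (mode == "chi2") {
    t <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(statistic = unname(t$statistic), p_value = t$p.value, method = "chi2")
  } else {
    t <- stats::fisher.test(m, alternative = "two.sided")
    list(statistic = unname(t$estimate), p_value = t$p.value, method = "fisher")
  }
}

#' Compare mutation-spectrum frequencies between groups
#'
#' For each contrast a 2x2 table of mutated vs unmutated eligible bases is
#' tested two-sided. Contrasts: total-C/G between groups, hotspot-C/G between
#' groups, and hotspot vs non-hotspot within each group. The chi-square test
#' uses no continuity correction; the Fisher test is the exact two-sided
#' hypergeometric rule (sum of tables no more probable than the observed one).
#' Only C/G transitions are counted by default — the class that replication of
#' unrepaired U:G mismatches produces.
#'
#' @param summary A [spectrum_summary()] result.
#' @param group_a,group_b Group labels to contrast (defaults: first two).
#' @param mode `"chi2"` (default) or `"fisher"`.
#' @param classes Count columns to pool as "mutated"; default C/G transitions.
#' @return Tibble of contrasts with the 2x2 cells, statistic and p-value.
#' @export
compare_spectra <- function(summary, group_a = NULL, group_b = NULL,
                            mode = c("chi2", "fisher"),
                            classes = "n_ts_cg") {
  mode <- match.arg(mode)
  pg <- summary$per_group
  groups <- pg$group
  group_a <- group_a %||% groups[1]
  group_b <- group_b %||% groups[2]
  comp <- summary$composition
  if (comp$n_cg == 0L || comp$n_cg_hotspot == 0L) abort("zero denominator in target composition")
  hot_classes <- paste0(classes, "_hotspot")

  cnt <- function(g, cols) sum(unlist(pg[pg$group == g, cols, drop = FALSE]))
  row_total <- function(g) c(cnt(g, classes), comp$n_cg - cnt(g, classes))
  row_hot <- function(g) c(cnt(g, hot_classes), comp$n_cg_hotspot - cnt(g, hot_classes))
  row_nonhot <- function(g) {
    nh <- cnt(g, classes) - cnt(g, hot_classes)
    c(nh, (comp$n_cg - comp$n_cg_hotspot) - nh)
  }

  contrasts <- list(
    list(name = "total_cg_between_groups", a = row_total(group_a), b = row_total(group_b),
         ga = group_a, gb = group_b),
    list(name = "hotspot_cg_between_groups", a = row_hot(group_a), b = row_hot(group_b),
         ga = group_a, gb = group_b),
    list(name = "hotspot_vs_total_within_group", a = row_hot(group_a), b = row_nonhot(group_a),
         ga = group_a, gb = group_a),
    list(name = "hotspot_vs_total_within_group", a = row_hot(group_b), b = row_nonhot(group_b),
         ga = group_b, gb = group_b)
  )
  map_dfr(contrasts, function(ct) {
    m <- rbind(ct$a, ct$b)
    tt <- two_by_two_test(m, mode)
    tibble(contrast = ct$name, group_a = ct$ga, group_b = ct$gb,
           x11 = m[1, 1], x12 = m[1, 2], x21 = m[2, 1], x22 = m[2, 2],
           statistic = tt$statistic, p_value = tt$p_value, method = tt$method)
  })
}
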