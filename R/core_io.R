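#' Column template for the normalized variant table
#'
#' All pipeline stages exchange a flat tibble with one row per called
#' ALT allele per sample. Positions are 1-based; `caller_filter` collapses the
#' upstream caller's FILTER column to `PASS` vs `NO_PASS`.
#'
#' @return A zero-row tibble with the canonical columns and types.
#' @export
empty_variant_table <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    sample = character(), depth = integer(), alt_count = integer(),
    vaf = double(), caller_filter = character(),
    gene = character(), consequence = character(), variant_class = character()
  )
}

variant_sort <- function(x) {
  arrange(x, .data$chrom, .data$pos, .data$sample, .data$ref, .data$alt)
}

#' Build variant keys
#'
#' A key identifies a variant independent of sample: `chrom:pos:ref:alt`,
#' with alleles already normalized.
#'
#' @param x Tibble with `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector of keys.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Normalize allele representation by parsimony trimming
#'
#' Removes bases shared by the end of `ref` and `alt`, then bases shared by
#' the start (adjusting `pos`), so the same INDEL called with different
#' padding yields one key. Pure string operation; no reference needed.
#'
#' @param pos,ref,alt Parallel vectors of 1-based position and allele strings.
#' @return Tibble with normalized `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    # trim common suffix, keeping at least one base each
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim common prefix
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  tibble(pos = pos, ref = ref, alt = alt)
}

finalize_variant_table <- function(x) {
  norm <- normalize_alleles(x$pos, x$ref, x$alt)
  x$pos <- norm$pos; x$ref <- norm$ref; x$alt <- norm$alt
  x <- mutate(x,
    depth = as.integer(.data$depth),
    alt_count = as.integer(.data$alt_count),
    vaf = ifelse(.data$depth > 0L, .data$alt_count / .data$depth, NA_real_),
    variant_class = ifelse(nchar(.data$ref) == 1L & nchar(.data$alt) == 1L, "SNV", "INDEL")
  )
  if (!"gene" %in% names(x)) x$gene <- ""
  if (!"consequence" %in% names(x)) x$consequence <- ""
  bad <- which(x$alt_count > x$depth)
  if (length(bad) > 0L) {
    warn(sprintf("%d record(s) have alt_count > depth (first: %s:%d)",
                 length(bad), x$chrom[bad[1]], x$pos[bad[1]]))
  }
  dup <- duplicated(paste(variant_key(x), x$sample))
  if (any(dup)) {
    abort(sprintf("duplicate variant key within sample (first: %s in %s)",
                  variant_key(x)[which(dup)[1]], x$sample[which(dup)[1]]))
  }
  variant_sort(select(x, all_of(names(empty_variant_table()))))
}

#' Load variant calls from a VCF into the normalized variant table
#'
#' One row per ALT allele (multi-allelic records are split). Depth and
#' alt-supporting reads are taken from the per-sample `DP`/`AD` FORMAT fields
#' first, falling back to the INFO column; a record with neither is an error,
#' never a silent zero, because downstream VAF cutoffs depend on them.
#' Any FILTER value other than exactly `PASS` (including `.`) becomes
#' `NO_PASS`.
#'
#' @param vcf_path Path to a VCF 4.x file.
#' @param sample Sample identifier stamped on every row. If the VCF carries
#'   several genotype columns, the column with this name is used (otherwise
#'   the first).
#' @return A variant table tibble (see [empty_variant_table()]).
#' @export
load_variants <- function(vcf_path, sample) {
  if (!file.exists(vcf_path)) abort(paste0("no such VCF: ", vcf_path))
  v <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                error = function(e) abort(paste0("unparseable VCF '", vcf_path, "': ", conditionMessage(e))))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) return(empty_variant_table())

  has_gt <- ncol(v@gt) >= 2L
  if (has_gt) {
    gt_samples <- colnames(v@gt)[-1]
    col <- if (sample %in% gt_samples) sample else gt_samples[1]
    dp_raw <- vcfR::extract.gt(v, "DP")[, col]
    ad_raw <- vcfR::extract.gt(v, "AD")[, col]
  } else {
    dp_raw <- rep(NA_character_, nrow(fix))
    ad_raw <- rep(NA_character_, nrow(fix))
  }
  # INFO fallback
  info_dp <- suppressWarnings(vcfR::extract.info(v, "DP"))
  info_ad <- suppressWarnings(vcfR::extract.info(v, "AD"))
  dp_raw <- ifelse(is.na(dp_raw), info_dp, dp_raw)
  ad_raw <- ifelse(is.na(ad_raw), info_ad, ad_raw)

  missing <- which(is.na(dp_raw) | is.na(ad_raw))
  if (length(missing) > 0L) {
    i <- missing[1]
    abort(sprintf("record %s:%s %s>%s lacks DP/AD depth fields",
                  fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], fix[i, "ALT"]))
  }

  rows <- map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ad <- as.integer(strsplit(ad_raw[i], ",", fixed = TRUE)[[1]])
    if (length(ad) < length(alts) + 1L) {
      # AD without the ref count (single number per alt)
      ad <- c(NA_integer_, ad)
    }
    filt <- unname(fix[i, "FILTER"])
    tibble(
      chrom = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
      ref = unname(fix[i, "REF"]), alt = alts,
      sample = sample,
      depth = as.integer(dp_raw[i]),
      alt_count = ad[-1][seq_along(alts)],
      caller_filter = if (!is.na(filt) && identical(filt, "PASS")) "PASS" else "NO_PASS"
    )
  })
  if (anyNA(rows$alt_count)) abort("AD field shorter than ALT allele count")
  finalize_variant_table(rows)
}

#' Load a known-sites list (dbSNP-like / strain-variant-like) from a VCF
#'
#' Only variant keys are retained; depth fields are not required.
#'
#' @param vcf_path Path to a sites-only VCF.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt` (normalized alleles).
#' @export
load_known_sites <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(), alt = character()))
  }
  rows <- map_dfr(seq_len(nrow(fix)), function(i) {
    tibble(chrom = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
           ref = unname(fix[i, "REF"]),
           alt = strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
  })
  norm <- normalize_alleles(rows$pos, rows$ref, rows$alt)
  distinct(tibble(chrom = rows$chrom, pos = norm$pos, ref = norm$ref, alt = norm$alt))
}

#' Write the variant table as deterministic TSV
#'
#' Rows are emitted sorted by chromosome, position and sample so repeat runs
#' are byte-identical. Empty gene/consequence cells stay empty strings;
#' genuinely missing numbers are written as `NA`.
#'
#' @param x Variant table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  readr::write_tsv(variant_sort(x), path, na = "NA")
  invisible(path)
}

#' Read a variant table written by [write_variant_table()]
#'
#' @param path TSV path.
#' @return Variant table tibble.
#' @export
read_variant_table <- function(path) {
  x <- readr::read_tsv(path, na = "NA", col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", sample = "c",
    depth = "i", alt_count = "i", vaf = "d", caller_filter = "c",
    gene = "c", consequence = "c", variant_class = "c"
  ))
  variant_sort(as_tibble(x))
}

# ---- target space -----------------------------------------------------------

new_target_space <- function(intervals, seqs) {
  structure(list(intervals = intervals, seqs = seqs), class = "target_space")
}

#' @export
print.target_space <- function(x, ...) {
  cat(sprintf("<target_space> %d interval(s) over %d sequence(s), %d bp targeted\n",
              nrow(x$intervals), length(x$seqs), sum(x$intervals$end - x$intervals$start)))
  invisible(x)
}

#' Load capture targets (BED) over a reference genome (FASTA)
#'
#' BED intervals are 0-based half-open; overlapping or book-ended intervals
#' are merged and the result sorted. Internally all variant positions stay
#' 1-based; this module owns every coordinate conversion.
#'
#' @param bed_path 3+ column BED file.
#' @param fasta_path Reference FASTA (read whole; no index required).
#' @return A `target_space` object: merged intervals plus the reference
#'   sequences ([Biostrings::DNAStringSet]).
#' @export
load_targets <- function(bed_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bed <- readr::read_tsv(bed_path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"), progress = FALSE)
  if (nrow(bed) == 0L) abort("BED file has no intervals")
  iv <- tibble(chrom = bed[[1]], start = as.integer(bed[[2]]), end = as.integer(bed[[3]]))
  target_space_from_intervals(iv, seqs)
}

target_space_from_intervals <- function(iv, seqs) {
  if (any(iv$end <= iv$start)) abort("BED interval with end <= start")
  missing <- setdiff(unique(iv$chrom), names(seqs))
  if (length(missing) > 0L) {
    abort(paste0("chromosome(s) absent from FASTA: ", paste(missing, collapse = ", ")))
  }
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  beyond <- iv$end > lens[iv$chrom]
  if (any(beyond)) {
    i <- which(beyond)[1]
    abort(sprintf("interval %s:%d-%d extends past chromosome end (%d bp)",
                  iv$chrom[i], iv$start[i], iv$end[i], lens[iv$chrom[i]]))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(start = iv$start + 1L, end = iv$end)))
  gr <- GenomicRanges::sort(gr)
  merged <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  new_target_space(merged, seqs)
}

#' Extract target interval sequences
#'
#' @param targets A `target_space`.
#' @return Character vector, one element per merged interval.
#' @export
target_sequences <- function(targets) {
  map_chr(seq_len(nrow(targets$intervals)), function(i) {
    iv <- targets$intervals[i, ]
    as.character(Biostrings::subseq(targets$seqs[[iv$chrom]], iv$start + 1L, iv$end))
  })
}

# ---- minimal deterministic VCF emitter (simulator output) -------------------

#' Write a single-sample variant table as VCF
#'
#' Deterministic emitter used by the cohort simulator: fixed header (no date
#' stamp), `DP`/`AD` FORMAT fields, rows sorted by locus. `NO_PASS` records
#' are written with the FILTER token `artifact`.
#'
#' @param x Variant table for one sample.
#' @param path Output path.
#' @param contigs Named integer vector of chromosome lengths.
#' @param sample Sample column name; default the table's sample id.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(x, path, contigs, sample = NULL) {
  sample <- sample %||% (if (nrow(x) > 0L) x$sample[1] else "SAMPLE")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=artifact,Description=\"Flagged by the caller\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  x <- variant_sort(x)
  body <- if (nrow(x) == 0L) character() else sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\t.\tDP:AD\t%d:%d,%d",
    x$chrom, x$pos, x$ref, x$alt,
    ifelse(x$caller_filter == "PASS", "PASS", "artifact"),
    x$depth, x$depth - x$alt_count, x$alt_count
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
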