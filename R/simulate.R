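#' Built-in genotype group presets
#'
#' Two presets mirror the qualitative contrast between the cohort's genotype
#' groups: `"wt_like"` (endogenous AID on a UNG-null background: fewer
#' mutations, moderate hotspot focusing, a single subclone) and `"ki_like"`
#' (AID supra-expression on the same background: higher mutation load,
#' stronger WRC/GYW focusing, more and heavier subclones).
#'
#' @param name `"wt_like"` or `"ki_like"`.
#' @return Named list of group parameters.
#' @export
group_preset <- function(name = c("wt_like", "ki_like")) {
  name <- match.arg(name)
  if (name == "wt_like") {
    list(n_tumors = 7L, mutations_per_tumor = 450L, p_cg_transition = 0.65,
         hotspot_w = 2, n_subclones = 1L, subclone_ccf = 0.35,
         clonal_ccf = 0.95, subclone_fraction = 0.25)
  } else {
    list(n_tumors = 8L, mutations_per_tumor = 800L, p_cg_transition = 0.80,
         hotspot_w = 5, n_subclones = 3L, subclone_ccf = c(0.50, 0.35, 0.20),
         clonal_ccf = 0.95, subclone_fraction = 0.50)
  }
}

#' Simulation configuration
#'
#' Defines the study conditions the synthetic cohort emulates: a 15-tumor
#' two-genotype cohort plus one healthy-tissue control, shared germline
#' variants, recurrent caller artifacts, an AID-like C:G-transition /
#' hotspot-enriched somatic process with clonal structure, and binomial read
#' support on Poisson depths. Expected somatic VAF is `purity * ccf / 2`
#' (copy-neutral diploid autosome).
#'
#' @param genome_length Reference length in bases (single chromosome).
#' @param gc_content Fraction of C+G in the simulated reference.
#' @param groups Named list of group parameter lists (see [group_preset()]).
#' @param n_germline Shared germline variants injected into every sample.
#' @param mean_depth Poisson mean of per-variant read depth.
#' @param purity Tumor purity (cancer-cell fraction of the specimen).
#' @param indel_fraction Fraction of somatic mutations that are 1-3 bp INDELs.
#' @param n_artifacts Recurrent artifact loci called in every sample.
#' @param artifact_no_pass_fraction Fraction of true somatic calls the caller
#'   flags NO_PASS.
#' @param artifact_sample_no_pass Per-sample probability that a recurrent
#'   artifact locus is flagged NO_PASS in that sample.
#' @param germline_hom_fraction Fraction of germline variants that are
#'   homozygous (expected VAF 1.0 vs 0.5).
#' @param healthy_somatic_recall Fraction of germline variants also called by
#'   the somatic caller on the healthy tissue.
#' @param known_sites_fraction Fraction of germline variants present in the
#'   known-sites list.
#' @param n_cnv_per_tumor Copy-number regions emitted per tumor (exclusion
#'   zones for clustering; no VAF distortion is modeled).
#' @param seed Integer seed; fully determines all outputs.
#' @param ... Overrides merged into the defaults.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 1000000L, gc_content = 0.42,
                       groups = list(wt_like = group_preset("wt_like"),
                                     ki_like = group_preset("ki_like")),
                       n_germline = 50L, mean_depth = 150, purity = 0.8,
                       indel_fraction = 0.24, n_artifacts = 25L,
                       artifact_no_pass_fraction = 0.05,
                       artifact_sample_no_pass = 0.15,
                       germline_hom_fraction = 0.3,
                       healthy_somatic_recall = 0.9,
                       known_sites_fraction = 0.9,
                       n_cnv_per_tumor = 2L, seed = 1L, ...) {
  cfg <- list(genome_length = as.integer(genome_length), gc_content = gc_content,
              groups = groups, n_germline = as.integer(n_germline),
              mean_depth = mean_depth, purity = purity,
              indel_fraction = indel_fraction, n_artifacts = as.integer(n_artifacts),
              artifact_no_pass_fraction = artifact_no_pass_fraction,
              artifact_sample_no_pass = artifact_sample_no_pass,
              germline_hom_fraction = germline_hom_fraction,
              healthy_somatic_recall = healthy_somatic_recall,
              known_sites_fraction = known_sites_fraction,
              n_cnv_per_tumor = as.integer(n_cnv_per_tumor),
              seed = as.integer(seed))
  cfg <- modifyList(cfg, list(...))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c("gc_content", "purity", "indel_fraction", "artifact_no_pass_fraction",
          "artifact_sample_no_pass", "germline_hom_fraction",
          "healthy_somatic_recall", "known_sites_fraction")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0(f, " must be in [0, 1]"))
  }
  if (cfg$genome_length < 1000L) abort("genome_length must be >= 1000")
  for (g in names(cfg$groups)) {
    gp <- cfg$groups[[g]]
    if (gp$hotspot_w < 1) abort("hotspot_w must be >= 1")
    if (gp$p_cg_transition < 0 || gp$p_cg_transition > 1) abort("p_cg_transition must be in [0, 1]")
    if (length(gp$subclone_ccf) != gp$n_subclones) abort("subclone_ccf length must equal n_subclones")
    if (any(gp$subclone_ccf >= gp$clonal_ccf)) abort("subclone_ccf must be strictly below clonal_ccf")
    if (any(gp$subclone_ccf <= 0 | gp$subclone_ccf >= 1)) abort("subclone_ccf must lie in (0, 1)")
  }
  invisible(cfg)
}

#' Simulate the reference genome and target space
#'
#' Draws an i.i.d. base sequence at the requested GC content (single
#' chromosome `chr1`) and targets the whole genome as one interval —
#' a desk-scale stand-in for an exome capture space.
#'
#' @param config A [sim_config()].
#' @return A `target_space`.
#' @export
simulate_reference <- function(config) {
  withr::with_seed(config$seed, {
    p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
           G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
    bases <- sample(names(p), config$genome_length, replace = TRUE, prob = p)
    seqs <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(seqs) <- "chr1"
    new_target_space(tibble(chrom = "chr1", start = 0L, end = config$genome_length), seqs)
  })
}

#' Draw mutated C/G sites with hotspot weighting
#'
#' Samples `n` distinct C/G target sites with relative weight `w` on hotspot
#' (non-edge) sites — the simulator's site model for AID-like C:G transitions,
#' whose analytic per-base enrichment expectation is `w` itself.
#'
#' @param targets A `target_space` (or a precomputed [target_sites()] tibble
#'   via `sites`).
#' @param n Number of sites to draw.
#' @param w Hotspot weight (>= 1).
#' @param sites Optional precomputed site table to avoid rescanning.
#' @return Site tibble subset with `hotspot` flags.
#' @export
sample_cg_transition_sites <- function(targets, n, w, sites = NULL) {
  st <- sites %||% target_sites(targets)
  cg <- filter(st, .data$base %in% c("C", "G"))
  if (n > nrow(cg)) abort("not enough eligible C/G sites for requested mutation count")
  wts <- ifelse(cg$hotspot, w, 1)
  cg[sample.int(nrow(cg), n, prob = wts), , drop = FALSE]
}

other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)
transition_of <- c(A = "G", G = "A", C = "T", T = "C")

draw_read_support <- function(n, mean_depth, evaf) {
  depth <- pmax(rpois(n, mean_depth), 1L)
  alt <- pmax(rbinom(n, depth, evaf), 1L)
  tibble(depth = as.integer(depth), alt_count = as.integer(alt))
}

#' Simulate the full cohort with ground truth
#'
#' Generates the reference, shared germline variants, recurrent artifact loci,
#' and per-tumor somatic mutations assigned to a clonal population plus
#' group-specific subclones. Each somatic mutation draws its class (C:G
#' transition with probability `p_cg_transition`, otherwise uniform over the
#' remaining substitution classes or an INDEL) and its site (hotspot C/G sites
#' weighted `hotspot_w`); read support is `alt ~ Binomial(depth, purity x ccf
#' / 2)` on `depth ~ Poisson(mean_depth)`. The same seed always yields
#' byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list: `targets`, named `tumors` tables,
#'   `healthy_germline` / `healthy_somatic` tables, `known_sites` keys,
#'   per-tumor `cnv` intervals, `groups` map, and the `truth` table recording
#'   per-variant origin, true cancer-cell fraction, class and hotspot status.
#' @export
simulate_cohort <- function(config) {
  targets <- simulate_reference(config)
  chrom_str <- as.character(targets$seqs[["chr1"]])
  st <- target_sites(targets)

  withr::with_seed(config$seed + 1L, {
    n_sites <- nrow(st)
    total_fixed <- config$n_germline + config$n_artifacts
    if (total_fixed >= n_sites) abort("not enough eligible sites for germline + artifact loci")
    fixed_idx <- sample.int(n_sites, total_fixed)
    germ_sites <- st[fixed_idx[seq_len(config$n_germline)], ]
    art_sites <- st[fixed_idx[config$n_germline + seq_len(config$n_artifacts)], ]
    reserved <- rep(FALSE, n_sites); reserved[fixed_idx] <- TRUE

    # germline definitions shared by every sample
    germ <- germ_sites |>
      mutate(ref = .data$base,
             alt = map_chr(.data$base, ~ sample(other_bases(.x), 1L)),
             evaf = ifelse(runif(n()) < config$germline_hom_fraction, 1.0, 0.5))
    art <- art_sites |>
      mutate(ref = .data$base,
             alt = map_chr(.data$base, ~ sample(other_bases(.x), 1L)),
             evaf = runif(n(), 0.05, 0.3))

    groups_tbl <- map_dfr(names(config$groups), function(g) {
      np <- config$groups[[g]]$n_tumors
      tibble(sample = sprintf("%s%d", toupper(sub("_like$", "", g)), seq_len(np)), group = g)
    })

    truth <- list(); tumors <- list(); cnv <- list()

    # shared loci drawn once; per-sample read support drawn per sample
    calls_for <- function(def, sample_id) {
      rs <- draw_read_support(nrow(def), config$mean_depth, rep(1, nrow(def)) * def$evaf)
      tibble(chrom = def$chrom, pos = def$pos, ref = def$ref, alt = def$alt,
             sample = sample_id, depth = rs$depth, alt_count = rs$alt_count,
             caller_filter = "PASS")
    }

    for (si in seq_len(nrow(groups_tbl))) {
      smp <- groups_tbl$sample[si]
      gp <- config$groups[[groups_tbl$group[si]]]
      n_mut <- gp$mutations_per_tumor
      n_indel <- round(config$indel_fraction * n_mut)
      n_snv <- n_mut - n_indel

      cls_counts <- as.vector(stats::rmultinom(1, n_snv, c(
        cg_transition = gp$p_cg_transition,
        cg_transversion = (1 - gp$p_cg_transition) / 3,
        at_transition = (1 - gp$p_cg_transition) / 3,
        at_transversion = (1 - gp$p_cg_transition) / 3)))
      n_cg_mut <- cls_counts[1] + cls_counts[2]
      n_at_mut <- cls_counts[3] + cls_counts[4]

      avail <- st[!reserved, ]
      cg_pool <- filter(avail, .data$base %in% c("C", "G"))
      at_pool <- filter(avail, .data$base %in% c("A", "T"))
      if (n_cg_mut > nrow(cg_pool) || n_at_mut > nrow(at_pool) || n_indel > nrow(avail))
        abort("not enough eligible sites for requested mutation count")

      cg_pick <- cg_pool[sample.int(nrow(cg_pool), n_cg_mut,
                                    prob = ifelse(cg_pool$hotspot, gp$hotspot_w, 1)), ]
      at_pick <- at_pool[sample.int(nrow(at_pool), n_at_mut), ]
      used <- c(paste(cg_pick$chrom, cg_pick$pos), paste(at_pick$chrom, at_pick$pos))
      indel_pool <- filter(avail, !paste(.data$chrom, .data$pos) %in% used,
                           .data$pos + 4L <= config$genome_length)
      indel_pick <- indel_pool[sample.int(nrow(indel_pool), n_indel), ]

      mk_alt <- function(base, class) {
        if (class == "cg_transition" || class == "at_transition") transition_of[[base]]
        else if (class == "cg_transversion") sample(if (base == "C") c("A", "G") else c("C", "T"), 1L)
        else sample(if (base == "A") c("C", "T") else c("A", "G"), 1L)
      }
      snv_def <- bind_rows(
        mutate(cg_pick, class = rep(c("cg_transition", "cg_transversion"), cls_counts[1:2])),
        mutate(at_pick, class = rep(c("at_transition", "at_transversion"), cls_counts[3:4]))
      ) |>
        mutate(ref = .data$base,
               alt = map2_chr(.data$base, .data$class, mk_alt))

      indel_def <- if (n_indel > 0L) {
        lens <- sample.int(3L, n_indel, replace = TRUE)
        ins <- runif(n_indel) < 0.5
        refs <- character(n_indel); alts <- character(n_indel)
        for (j in seq_len(n_indel)) {
          b <- indel_pick$base[j]; p <- indel_pick$pos[j]
          if (ins[j]) {
            refs[j] <- b
            alts[j] <- paste0(b, paste(sample(c("A", "C", "G", "T"), lens[j], replace = TRUE),
                                       collapse = ""))
          } else {
            refs[j] <- substr(chrom_str, p, p + lens[j])
            alts[j] <- b
          }
        }
        mutate(indel_pick, class = "indel", ref = refs, alt = alts)
      } else {
        mutate(indel_pick, class = character(0), ref = character(0), alt = character(0))
      }

      som <- bind_rows(snv_def, indel_def)
      n_tot <- nrow(som)
      sub_p <- gp$subclone_fraction / gp$n_subclones
      clone <- sample.int(gp$n_subclones + 1L, n_tot, replace = TRUE,
                          prob = c(1 - gp$subclone_fraction, rep(sub_p, gp$n_subclones))) - 1L
      ccf <- ifelse(clone == 0L, gp$clonal_ccf, gp$subclone_ccf[pmax(clone, 1L)])
      evaf <- config$purity * ccf / 2
      rs <- draw_read_support(n_tot, config$mean_depth, evaf)
      som_calls <- tibble(
        chrom = som$chrom, pos = som$pos, ref = som$ref, alt = som$alt,
        sample = smp, depth = rs$depth, alt_count = rs$alt_count,
        caller_filter = ifelse(runif(n_tot) < config$artifact_no_pass_fraction,
                               "NO_PASS", "PASS"))

      germ_calls <- calls_for(germ, smp)
      art_calls <- calls_for(art, smp) |>
        mutate(caller_filter = ifelse(runif(n()) < config$artifact_sample_no_pass,
                                      "NO_PASS", "PASS"))
      tumors[[smp]] <- finalize_variant_table(bind_rows(som_calls, germ_calls, art_calls))
      truth[[smp]] <- tibble(
        chrom = som$chrom, pos = som$pos, ref = som$ref, alt = som$alt,
        sample = smp,
        origin = ifelse(clone == 0L, "clonal", paste0("subclonal:", clone)),
        true_ccf = ccf, class = som$class, hotspot = som$hotspot)

      # CNV exclusion zones, deliberately VAF-neutral
      cnv[[smp]] <- if (config$n_cnv_per_tumor > 0L) {
        len <- pmax(1000L, as.integer(config$genome_length * 0.03))
        s <- sort(sample.int(config$genome_length - len, config$n_cnv_per_tumor))
        tibble(chrom = "chr1", start = s, end = pmin(s + len, config$genome_length))
      } else {
        tibble(chrom = character(), start = integer(), end = integer())
      }
    }

    healthy_germline <- finalize_variant_table(calls_for(germ, "healthy"))
    hs_keep <- runif(nrow(germ)) < config$healthy_somatic_recall
    healthy_somatic <- finalize_variant_table(bind_rows(
      calls_for(germ[hs_keep, ], "healthy"),
      calls_for(art, "healthy")))

    ks_keep <- runif(nrow(germ)) < config$known_sites_fraction
    known_sites <- select(germ[ks_keep, ], "chrom", "pos", "ref", "alt")

    truth_all <- bind_rows(
      tibble(chrom = germ$chrom, pos = germ$pos, ref = germ$ref, alt = germ$alt,
             sample = NA_character_, origin = "germline", true_ccf = NA_real_,
             class = "germline_snv", hotspot = germ$hotspot),
      tibble(chrom = art$chrom, pos = art$pos, ref = art$ref, alt = art$alt,
             sample = NA_character_, origin = "artifact", true_ccf = NA_real_,
             class = "artifact_snv", hotspot = art$hotspot),
      bind_rows(truth))

    structure(list(config = config, targets = targets, tumors = tumors,
                   healthy_germline = healthy_germline,
                   healthy_somatic = healthy_somatic,
                   known_sites = known_sites, cnv = cnv,
                   groups = groups_tbl, truth = truth_all),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d tumors (%s) + healthy control, %d germline loci, genome %d bp\n",
              nrow(x$groups), paste(table(x$groups$group), collapse = "/"),
              x$config$n_germline, x$config$genome_length))
  invisible(x)
}

#' Synthetic gene and consequence annotation for a simulated cohort
#'
#' Partitions the genome into equal-width synthetic genes, assigns every
#' emitted variant a gene and a consequence drawn from a fixed controlled
#' vocabulary (INDELs draw frameshift/inframe classes), and nominates random
#' gene subsets as the synthetic "driver" and "lymphoma" gene sets.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param n_genes Number of synthetic genes tiling the genome. The default
#'   scales with genome length (one gene per 200 bp) so that, like a real
#'   exome, most genes stay unmutated in any one tumor — the sparsity the
#'   exclusive-gene contrast depends on. At the default 1 Mb genome this
#'   gives 5000 genes.
#' @param n_driver,n_lymphoma Sizes of the synthetic gene sets; the defaults
#'   scale to 459 and 239 genes at the default genome, echoing the sizes of
#'   the curated driver and lymphoma sets the analysis is designed for.
#' @return List with `annotation` (key-level gene/consequence tibble),
#'   `gene_spans`, `driver_genes`, `lymphoma_genes`.
#' @export
emit_gene_annotations <- function(cohort, n_genes = NULL, n_driver = NULL,
                                  n_lymphoma = NULL) {
  cfg <- cohort$config
  n_genes <- n_genes %||% max(40L, cfg$genome_length %/% 200L)
  n_driver <- n_driver %||% min(459L, max(10L, n_genes %/% 11L))
  n_lymphoma <- n_lymphoma %||% min(239L, max(8L, n_genes %/% 21L))
  withr::with_seed(cfg$seed + 2L, {
    bounds <- as.integer(round(seq(0, cfg$genome_length, length.out = n_genes + 1L)))
    spans <- tibble(gene = sprintf("GENE%05d", seq_len(n_genes)),
                    chrom = "chr1", start = bounds[-length(bounds)], end = bounds[-1])
    keys <- bind_rows(
      map_dfr(cohort$tumors, ~ select(.x, "chrom", "pos", "ref", "alt")),
      select(cohort$healthy_germline, "chrom", "pos", "ref", "alt")
    ) |> distinct() |> arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
    gi <- findInterval(keys$pos - 1L, bounds, rightmost.closed = TRUE)
    gi <- pmin(pmax(gi, 1L), n_genes)
    is_snv <- nchar(keys$ref) == 1L & nchar(keys$alt) == 1L
    snv_vocab <- c("missense", "synonymous", "stop_gained", "splice", "utr")
    snv_p <- c(0.5, 0.3, 0.1, 0.05, 0.05)
    indel_vocab <- c("frameshift", "inframe_indel")
    cons <- character(nrow(keys))
    cons[is_snv] <- sample(snv_vocab, sum(is_snv), replace = TRUE, prob = snv_p)
    cons[!is_snv] <- sample(indel_vocab, sum(!is_snv), replace = TRUE, prob = c(0.7, 0.3))
    annotation <- mutate(keys, gene = spans$gene[gi], consequence = cons)
    driver <- sort(sample(spans$gene, n_driver))
    lymphoma <- sort(sample(spans$gene, n_lymphoma))
    list(annotation = annotation, gene_spans = spans,
         driver_genes = driver, lymphoma_genes = lymphoma)
  })
}

#' Attach gene/consequence annotation to a variant table
#'
#' @param variants Variant table.
#' @param annotation Annotation tibble from [emit_gene_annotations()] (or an
#'   equivalent TSV read back).
#' @return Variant table with `gene` and `consequence` filled.
#' @export
annotate_variants <- function(variants, annotation) {
  variants |>
    select(-"gene", -"consequence") |>
    left_join(select(annotation, "chrom", "pos", "ref", "alt", "gene", "consequence"),
              by = c("chrom", "pos", "ref", "alt")) |>
    mutate(gene = tidyr::replace_na(.data$gene, ""),
           consequence = tidyr::replace_na(.data$consequence, "")) |>
    variant_sort()
}

#' Write all cohort files to a directory
#'
#' Emits the reference FASTA, target BED, per-sample tumor VCFs, healthy
#' germline/somatic VCFs, known-sites VCF, per-tumor CNV BEDs, gene
#' annotation TSV, gene-set lists and the ground-truth TSV. All outputs are
#' deterministic text.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param annotations Optional [emit_gene_annotations()] result to write too.
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, annotations = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(dir, "cnv"), showWarnings = FALSE)
  contigs <- setNames(Biostrings::width(cohort$targets$seqs), names(cohort$targets$seqs))

  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(cohort$targets$seqs, fa, width = 80L)
  bed <- file.path(dir, "targets.bed")
  readr::write_tsv(cohort$targets$intervals, bed, col_names = FALSE)

  paths <- list(reference = fa, targets = bed)
  for (smp in names(cohort$tumors)) {
    p <- file.path(dir, "vcf", paste0(smp, ".vcf"))
    write_variants_vcf(cohort$tumors[[smp]], p, contigs)
    paths[[paste0("vcf_", smp)]] <- p
    pc <- file.path(dir, "cnv", paste0(smp, ".bed"))
    readr::write_tsv(cohort$cnv[[smp]], pc, col_names = FALSE)
    paths[[paste0("cnv_", smp)]] <- pc
  }
  hg <- file.path(dir, "vcf", "healthy_germline.vcf")
  hs <- file.path(dir, "vcf", "healthy_somatic.vcf")
  write_variants_vcf(cohort$healthy_germline, hg, contigs)
  write_variants_vcf(cohort$healthy_somatic, hs, contigs)
  ks <- file.path(dir, "vcf", "known_sites.vcf")
  ks_tbl <- mutate(cohort$known_sites, sample = "sites", depth = 1L, alt_count = 1L,
                   caller_filter = "PASS")
  write_variants_vcf(finalize_variant_table(ks_tbl), ks, contigs, sample = "sites")
  truth <- file.path(dir, "truth.tsv")
  readr::write_tsv(arrange(cohort$truth, .data$chrom, .data$pos, .data$sample,
                           .data$ref, .data$alt), truth, na = "NA")
  readr::write_tsv(cohort$groups, file.path(dir, "groups.tsv"))
  paths <- c(paths, list(healthy_germline = hg, healthy_somatic = hs,
                         known_sites = ks, truth = truth,
                         groups = file.path(dir, "groups.tsv")))
  if (!is.null(annotations)) {
    an <- file.path(dir, "annotation.tsv")
    readr::write_tsv(annotations$annotation, an)
    writeLines(annotations$driver_genes, file.path(dir, "driver_genes.txt"))
    writeLines(annotations$lymphoma_genes, file.path(dir, "lymphoma_genes.txt"))
    paths <- c(paths, list(annotation = an,
                           driver_genes = file.path(dir, "driver_genes.txt"),
                           lymphoma_genes = file.path(dir, "lymphoma_genes.txt")))
  }
  invisible(paths)
}
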