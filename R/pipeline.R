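#' Build a simulation config from a YAML file
#'
#' Top-level keys override [sim_config()] defaults; `groups` entries override
#' the named [group_preset()] fields.
#'
#' @param path YAML config path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- list(wt_like = group_preset("wt_like"), ki_like = group_preset("ki_like"))
  if (!is.null(y$groups)) {
    for (g in names(y$groups)) {
      base <- if (g %in% names(groups)) groups[[g]] else group_preset("wt_like")
      ov <- y$groups[[g]]
      if (!is.null(ov$subclone_ccf)) ov$subclone_ccf <- as.numeric(unlist(ov$subclone_ccf))
      groups[[g]] <- modifyList(base, ov)
    }
    groups <- groups[names(y$groups)]
  }
  y$groups <- NULL
  do.call(sim_config, c(list(groups = groups), y))
}

#' Run the whole analysis end-to-end on a simulated cohort
#'
#' Simulates the cohort, writes its files, reads them back through the
#' standard-format loaders, and runs every stage: panel-of-normals
#' construction and somatic filtering, mutation-spectrum summary and group
#' comparisons, per-tumor VAF clustering with clonal/subclonal labeling and
#' the pooled heterogeneity test, and cancer-gene annotation with
#' genotype-exclusive gene detection. All outputs are deterministic text
#' keyed entirely by the config seed: repeat runs produce byte-identical
#' trees.
#'
#' @param config A `sim_config`, a YAML path, or `NULL` for the defaults.
#' @param out_dir Output directory.
#' @param seed Optional integer overriding the config seed.
#' @param min_depth,max_vaf,k_max Clustering-stage parameters.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL,
                         min_depth = 100L, max_vaf = 0.8, k_max = 6L) {
  cfg <- if (is.null(config)) sim_config()
         else if (inherits(config, "sim_config")) config
         else read_sim_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- simulate and serialize ------------------------------------------------
  cohort <- simulate_cohort(cfg)
  ann <- emit_gene_annotations(cohort)
  sim_dir <- file.path(out_dir, "sim")
  paths <- write_cohort(cohort, sim_dir, annotations = ann)

  # -- read back through the format loaders ----------------------------------
  targets <- load_targets(paths$targets, paths$reference)
  groups_tbl <- readr::read_tsv(paths$groups, col_types = "cc", progress = FALSE)
  tumors <- map(setNames(groups_tbl$sample, groups_tbl$sample), function(smp)
    load_variants(file.path(sim_dir, "vcf", paste0(smp, ".vcf")), smp))
  healthy_germline <- load_variants(paths$healthy_germline, "healthy")
  healthy_somatic <- load_variants(paths$healthy_somatic, "healthy")
  known_sites <- load_known_sites(paths$known_sites)
  annotation <- readr::read_tsv(paths$annotation, col_types = "cicccc", progress = FALSE)

  # -- panel of normals + somatic filter -------------------------------------
  fcfg <- filter_config(n_all = nrow(groups_tbl),
                        n_most = max(nrow(groups_tbl) - 2L, 1L))
  pon <- build_pon(healthy_germline, healthy_somatic, tumors, fcfg)
  readr::write_tsv(pon, file.path(out_dir, "pon.tsv"))

  filt <- filter_somatic(bind_rows(tumors), pon,
                         list(healthy_germline, healthy_somatic),
                         list(known = known_sites))
  filtered <- annotate_variants(filt$variants, annotation)
  dir.create(file.path(out_dir, "filtered"), showWarnings = FALSE)
  for (smp in groups_tbl$sample) {
    write_variant_table(filter(filtered, .data$sample == smp),
                        file.path(out_dir, "filtered", paste0(smp, ".tsv")))
  }
  readr::write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"))

  # -- mutation spectrum -----------------------------------------------------
  composition <- target_composition(targets)
  spec <- spectrum_summary(filtered, targets, groups_tbl, composition)
  readr::write_tsv(spec$per_sample, file.path(out_dir, "spectrum_per_sample.tsv"))
  readr::write_tsv(spec$per_group, file.path(out_dir, "spectrum_group.tsv"))
  spec_tests <- bind_rows(compare_spectra(spec, mode = "chi2"),
                          compare_spectra(spec, mode = "fisher"))
  readr::write_tsv(spec_tests, file.path(out_dir, "spectrum_tests.tsv"))

  # -- clonal architecture ---------------------------------------------------
  arch <- list()
  clon_rows <- list()
  for (i in seq_len(nrow(groups_tbl))) {
    smp <- groups_tbl$sample[i]
    v <- filter(filtered, .data$sample == smp)
    cnv <- readr::read_tsv(file.path(sim_dir, "cnv", paste0(smp, ".bed")),
                           col_names = c("chrom", "start", "end"),
                           col_types = "cii", progress = FALSE)
    fc <- filter_for_clustering(v, cnv, min_depth = min_depth, max_vaf = max_vaf)
    if (nrow(fc$kept) < 10L) {
      clon_rows[[smp]] <- tibble(sample = smp, group = groups_tbl$group[i],
                                 clustered = FALSE, k = NA_integer_,
                                 n_clonal = NA_integer_, n_subclonal = NA_integer_,
                                 subclonal_proportion = NA_real_)
      next
    }
    fit <- fit_vaf_clusters(fc$kept$alt_count, fc$kept$depth, k_max = k_max,
                            seed = cfg$seed + 100L + i)
    fit <- label_clonality(fit)
    arch[[smp]] <- fit
    readr::write_tsv(tidy(fit), file.path(out_dir, paste0("clusters_", smp, ".tsv")))
    clon_rows[[smp]] <- tibble(sample = smp, group = groups_tbl$group[i],
                               clustered = TRUE, k = fit$k,
                               n_clonal = fit$clusters$n_variants[1],
                               n_subclonal = sum(fit$clusters$n_variants[-1]),
                               subclonal_proportion = fit$subclonal_proportion)
  }
  clon_summary <- bind_rows(clon_rows)
  readr::write_tsv(clon_summary, file.path(out_dir, "clonality_summary.tsv"))

  grp_names <- unique(groups_tbl$group)
  ith <- NULL
  if (length(grp_names) >= 2L) {
    ga <- arch[intersect(groups_tbl$sample[groups_tbl$group == grp_names[1]], names(arch))]
    gb <- arch[intersect(groups_tbl$sample[groups_tbl$group == grp_names[2]], names(arch))]
    ith <- compare_ith(ga, gb, grp_names[1], grp_names[2])
    readr::write_tsv(bind_rows(
      tibble(group = grp_names[1], n_clonal = ith$pooled[1, 1],
             n_subclonal = ith$pooled[1, 2],
             subclonal_proportion = ith$subclonal_proportion[1],
             fisher_p = ith$p_value),
      tibble(group = grp_names[2], n_clonal = ith$pooled[2, 1],
             n_subclonal = ith$pooled[2, 2],
             subclonal_proportion = ith$subclonal_proportion[2],
             fisher_p = ith$p_value)
    ), file.path(out_dir, "ith_test.tsv"))
  }

  # -- cancer genes ----------------------------------------------------------
  sets <- load_gene_sets(paths$driver_genes, paths$lymphoma_genes)
  mats <- map(setNames(grp_names, grp_names), function(g)
    annotate_cancer_genes(filter(filtered,
                                 .data$sample %in% groups_tbl$sample[groups_tbl$group == g]),
                          sets))
  readr::write_tsv(bind_rows(imap(mats, ~ mutate(.x$cells, group = .y))),
                   file.path(out_dir, "gene_matrix.tsv"))
  excl <- NULL; excl_spec <- NULL
  if (length(grp_names) >= 2L) {
    excl <- exclusive_genes(mats[[1]], mats[[2]], min_recurrence = 2L)
    readr::write_tsv(bind_rows(
      tibble(set = paste0("exclusive_", grp_names[1]), gene = excl$exclusive_a),
      tibble(set = paste0("exclusive_", grp_names[2]), gene = excl$exclusive_b),
      tibble(set = "shared", gene = excl$shared)
    ), file.path(out_dir, "exclusive_genes.tsv"))
    vb <- filter(filtered, toupper(.data$gene) %in% excl$exclusive_b,
                 .data$sample %in% groups_tbl$sample[groups_tbl$group == grp_names[2]])
    va <- filter(filtered, toupper(.data$gene) %in% excl$exclusive_a,
                 .data$sample %in% groups_tbl$sample[groups_tbl$group == grp_names[1]])
    excl_spec <- bind_rows(
      mutate(exclusive_spectrum(vb, targets, composition), genes = paste0("exclusive_", grp_names[2])),
      mutate(exclusive_spectrum(vb, targets, composition, other = va),
             genes = paste0("exclusive_", grp_names[2], "_vs_", grp_names[1]))
    )
    readr::write_tsv(excl_spec, file.path(out_dir, "exclusive_spectrum.tsv"))
  }

  invisible(list(config = cfg, cohort = cohort, targets = targets, pon = pon,
                 filtered = filtered, filter_report = filt$report,
                 composition = composition, spectrum = spec,
                 spectrum_tests = spec_tests, architectures = arch,
                 clonality_summary = clon_summary, ith = ith,
                 gene_sets = sets, gene_matrices = mats,
                 exclusive = excl, exclusive_spectrum = excl_spec))
}
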