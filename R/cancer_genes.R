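#' Default consequence severity order (least to most severe)
#'
#' An explicit, overridable ordering keeps the per-gene most-severe-consequence
#' reduction deterministic across runs (annotation tools version their own
#' internal orderings).
#'
#' @return Character vector, least severe first.
#' @export
default_severity_order <- function() {
  c("synonymous", "utr", "non_coding", "missense", "inframe_indel",
    "splice", "stop_gained", "nonsense", "frameshift")
}

#' Load cancer gene sets from plain-text lists
#'
#' One symbol per line; `#` comments and blank lines are ignored; symbols are
#' case-normalized (uppercased) and deduplicated.
#'
#' @param driver_path Path to the cancer-driver gene list.
#' @param lymphoma_path Path to the lymphoma-associated gene list.
#' @return A `gene_sets` list with `drivers`, `lymphoma` and their `union`.
#' @export
load_gene_sets <- function(driver_path, lymphoma_path) {
  read_set <- function(p) {
    x <- readLines(p)
    x <- trimws(sub("#.*$", "", x))
    x <- unique(toupper(x[nzchar(x)]))
    if (length(x) == 0L) abort(paste0("empty gene-set file: ", p))
    sort(x)
  }
  drivers <- read_set(driver_path)
  lymphoma <- read_set(lymphoma_path)
  structure(list(drivers = drivers, lymphoma = lymphoma,
                 union = sort(union(drivers, lymphoma))),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d drivers, %d lymphoma, %d in union\n",
              length(x$drivers), length(x$lymphoma), length(x$union)))
  invisible(x)
}

#' Presence/absence matrix of cancer-gene mutations with consequence reduction
#'
#' Restricts variants to genes in the gene-set union, marks each (gene, tumor)
#' cell as mutated when at least one retained variant maps there, and reduces
#' that cell's consequences to the single most severe one under
#' `severity_order`. Also returns per-tumor stacked variant counts by
#' consequence.
#'
#' @param variants Filtered, annotated variant table (all tumors; `gene` and
#'   `consequence` filled).
#' @param sets A [load_gene_sets()] result.
#' @param severity_order Consequence vocabulary, least severe first; every
#'   observed consequence in a cancer gene must appear in it.
#' @return A `gene_matrix` object: long `cells` tibble (gene, sample,
#'   n_variants, consequence), the `samples` vector and per-tumor
#'   `consequence_counts`.
#' @export
annotate_cancer_genes <- function(variants, sets,
                                  severity_order = default_severity_order()) {
  v <- variants |>
    mutate(gene = toupper(.data$gene)) |>
    filter(.data$gene %in% sets$union)
  unknown <- setdiff(unique(v$consequence), severity_order)
  unknown <- unknown[nzchar(unknown)]
  if (length(unknown) > 0L) {
    abort(paste0("consequence(s) absent from severity_order: ",
                 paste(unknown, collapse = ", ")))
  }
  sev <- function(x) {
    r <- match(x, severity_order)
    severity_order[max(r)]
  }
  cells <- v |>
    group_by(.data$gene, .data$sample) |>
    summarise(n_variants = n(), consequence = sev(.data$consequence), .groups = "drop") |>
    arrange(.data$gene, .data$sample)
  counts <- v |>
    count(.data$sample, .data$consequence, name = "n") |>
    arrange(.data$sample, .data$consequence)
  structure(list(cells = cells, samples = sort(unique(variants$sample)),
                 consequence_counts = counts, severity_order = severity_order),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %d gene(s) x %d tumor(s), %d mutated cells\n",
              n_distinct(x$cells$gene), length(x$samples), nrow(x$cells)))
  invisible(x)
}

#' Genotype-exclusive and shared cancer genes
#'
#' Partitions mutated cancer genes by group presence: exclusive to A,
#' exclusive to B, or shared. With `min_recurrence` > 1 a gene must be
#' mutated in at least that many tumors of a group to count as present there
#' at all.
#'
#' @param matrix_a,matrix_b `gene_matrix` objects for the two groups.
#' @param min_recurrence Minimum tumors per group for a gene to count
#'   (default 1).
#' @return List with `exclusive_a`, `exclusive_b`, `shared` (sorted character
#'   vectors).
#' @export
exclusive_genes <- function(matrix_a, matrix_b, min_recurrence = 1L) {
  present <- function(m) {
    m$cells |>
      count(.data$gene, name = "n_tumors") |>
      filter(.data$n_tumors >= min_recurrence) |>
      pull(.data$gene)
  }
  a <- present(matrix_a); b <- present(matrix_b)
  list(exclusive_a = sort(setdiff(a, b)),
       exclusive_b = sort(setdiff(b, a)),
       shared = sort(intersect(a, b)))
}

#' Mutation-spectrum proportions in exclusive cancer genes
#'
#' For SNVs falling in a given gene set (typically the genes exclusively
#' mutated in one genotype), computes the proportion of mutations at C/G vs
#' A/T bases and, among C/G mutations, within WRC/GYW hotspots vs not. Each
#' split is tested two-sided with Fisher's exact test against the
#' target-space base composition (observed mutated/unmutated eligible bases,
#' the same construction as [compare_spectra()]); when a second variant set
#' is supplied the two sets are compared against each other instead. Both
#' baselines are reasonable nulls for the same question and are labeled in
#' the output.
#'
#' @param variants Annotated SNV table restricted to the exclusive genes.
#' @param targets A `target_space`.
#' @param composition Optional precomputed [target_composition()].
#' @param other Optional second variant table for the set-vs-set mode.
#' @return Tibble of proportions and Fisher tests (one row per split and
#'   baseline); zero SNVs yield NA tests.
#' @export
exclusive_spectrum <- function(variants, targets, composition = NULL, other = NULL) {
  composition <- composition %||% target_composition(targets)
  split_counts <- function(v) {
    v <- filter(v, .data$variant_class == "SNV")
    if (nrow(v) == 0L) {
      return(list(n_cg = 0L, n_at = 0L, n_hot = 0L, n_nonhot = 0L))
    }
    cls <- classify_substitution(v$ref, v$alt)
    cg <- cls$base_class == "CG"
    hot <- as.logical(is_hotspot(targets, v$chrom, v$pos, v$ref))
    list(n_cg = sum(cg), n_at = sum(!cg),
         n_hot = sum(hot & cg), n_nonhot = sum(!hot & cg))
  }
  x <- split_counts(variants)
  mk_row <- function(split, baseline, m, prop) {
    p <- if (any(is.na(m)) || sum(m) == 0 || any(rowSums(m) == 0)) NA_real_
         else stats::fisher.test(m, alternative = "two.sided")$p.value
    tibble(split = split, baseline = baseline, proportion = prop,
           x11 = m[1, 1], x12 = m[1, 2], x21 = m[2, 1], x22 = m[2, 2], p_value = p)
  }
  out <- list()
  if (is.null(other)) {
    out$cg <- mk_row("cg_vs_at", "target_composition",
                     rbind(c(x$n_cg, x$n_at),
                           c(composition$n_cg, composition$n_at)),
                     if (x$n_cg + x$n_at > 0) x$n_cg / (x$n_cg + x$n_at) else NA_real_)
    out$hot <- mk_row("hotspot_vs_nonhotspot", "target_composition",
                      rbind(c(x$n_hot, x$n_nonhot),
                            c(composition$n_cg_hotspot,
                              composition$n_cg - composition$n_cg_hotspot)),
                      if (x$n_hot + x$n_nonhot > 0) x$n_hot / (x$n_hot + x$n_nonhot) else NA_real_)
  } else {
    y <- split_counts(other)
    out$cg <- mk_row("cg_vs_at", "other_group",
                     rbind(c(x$n_cg, x$n_at), c(y$n_cg, y$n_at)),
                     if (x$n_cg + x$n_at > 0) x$n_cg / (x$n_cg + x$n_at) else NA_real_)
    out$hot <- mk_row("hotspot_vs_nonhotspot", "other_group",
                      rbind(c(x$n_hot, x$n_nonhot), c(y$n_hot, y$n_nonhot)),
                      if (x$n_hot + x$n_nonhot > 0) x$n_hot / (x$n_hot + x$n_nonhot) else NA_real_)
  }
  bind_rows(out)
}
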