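#' Filtering configuration for the panel of normals
#'
#' The thresholds mirror the cohort design: `n_all` tumors in total (15),
#' recurrence threshold `n_most` (13) for set 3, and at most
#' `max_no_pass_set2` (2) NO_PASS labels tolerated in set 2.
#'
#' @param n_all Number of tumor samples in the cohort.
#' @param n_most Minimum tumors a variant must be called in for set 3.
#' @param max_no_pass_set2 Maximum samples in which a set-2 variant may be
#'   labeled NO_PASS.
#' @param healthy_membership Which healthy call set counts as "called in
#'   healthy tissue" for sets 2/3 and the healthy-removal rule: `"either"`
#'   (default), `"somatic"` or `"germline"`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(n_all = 15L, n_most = 13L, max_no_pass_set2 = 2L,
                          healthy_membership = c("either", "somatic", "germline")) {
  healthy_membership <- match.arg(healthy_membership)
  if (n_most > n_all) abort("n_most must be <= n_all")
  if (max_no_pass_set2 >= n_all) abort("max_no_pass_set2 must be < n_all")
  structure(list(n_all = as.integer(n_all), n_most = as.integer(n_most),
                 max_no_pass_set2 = as.integer(max_no_pass_set2),
                 healthy_membership = healthy_membership),
            class = "filter_config")
}

as_call_table <- function(x) {
  if (is.data.frame(x)) return(x)
  bind_rows(x)
}

#' Build the cohort-specific panel of normals
#'
#' Combines three variant sets keyed by (chrom, pos, ref, alt):
#' * **set1** — intersection of the germline-caller and somatic-caller calls
#'   on the healthy tissue;
#' * **set2** — keys called in the healthy tissue and in *all* `n_all`
#'   tumors, tolerating a NO_PASS label in at most `max_no_pass_set2` of
#'   them;
#' * **set3** — keys called in the healthy tissue and in at least `n_most`
#'   tumors, labeled PASS in every sample in which they were called.
#'
#' "Called in" a sample means present as a key in that sample's calls
#' regardless of PASS label, except where a rule names the label explicitly.
#'
#' @param healthy_germline,healthy_somatic Healthy-tissue call tables.
#' @param tumor_calls Per-tumor call tables: one tibble with a `sample`
#'   column, or a named list of tibbles.
#' @param cfg A [filter_config()].
#' @param allow_n_mismatch Set `TRUE` to proceed when the number of tumor
#'   samples differs from `cfg$n_all`.
#' @return Tibble of PON entries: key columns plus `set1`/`set2`/`set3`
#'   logicals and a collapsed `provenance` string.
#' @export
build_pon <- function(healthy_germline, healthy_somatic, tumor_calls, cfg = filter_config(),
                      allow_n_mismatch = FALSE) {
  tc <- as_call_table(tumor_calls)
  n_samples <- n_distinct(tc$sample)
  if (n_samples != cfg$n_all && !allow_n_mismatch) {
    abort(sprintf("cfg$n_all = %d but %d tumor samples provided (set allow_n_mismatch = TRUE to override)",
                  cfg$n_all, n_samples))
  }
  kg <- unique(variant_key(healthy_germline))
  ks <- unique(variant_key(healthy_somatic))
  healthy_mem <- switch(cfg$healthy_membership,
                        either = union(kg, ks), somatic = ks, germline = kg)

  per_key <- tc |>
    mutate(key = variant_key(tc)) |>
    group_by(.data$key, .data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(n_called = n_distinct(.data$sample),
              n_no_pass = sum(.data$caller_filter == "NO_PASS"),
              .groups = "drop")

  healthy_keys_tbl <- bind_rows(healthy_germline, healthy_somatic) |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    mutate(key = variant_key(pick(everything())), n_called = 0L, n_no_pass = 0L) |>
    filter(!.data$key %in% per_key$key)

  all_keys <- bind_rows(per_key, healthy_keys_tbl) |>
    mutate(
      set1 = .data$key %in% intersect(kg, ks),
      set2 = .data$key %in% healthy_mem & .data$n_called == cfg$n_all &
        .data$n_no_pass <= cfg$max_no_pass_set2,
      set3 = .data$key %in% healthy_mem & .data$n_called >= cfg$n_most &
        .data$n_no_pass == 0L
    ) |>
    filter(.data$set1 | .data$set2 | .data$set3) |>
    mutate(provenance = pmap_chr(list(.data$set1, .data$set2, .data$set3), function(a, b, c)
      paste(c("set1", "set2", "set3")[c(a, b, c)], collapse = ","))) |>
    select("chrom", "pos", "ref", "alt", "set1", "set2", "set3", "provenance") |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  all_keys
}

#' Remove panel-of-normals, healthy-tissue and known-site variants
#'
#' A tumor variant is retained iff its key is absent from the PON, from the
#' healthy-tissue calls, and from every known-site list. Removals are tallied
#' per sample by the *first* matching reason, in the fixed order
#' PON -> healthy -> known-sites, so reports are deterministic when rules
#' overlap.
#'
#' @param variants Per-tumor variant table (one tibble, `sample` column).
#' @param pon PON tibble from [build_pon()] (may be empty).
#' @param healthy_calls Healthy-tissue calls: a tibble or list of tibbles.
#' @param known_sites A key tibble, or a named list of key tibbles
#'   (chrom/pos/ref/alt).
#' @return List with `variants` (retained rows, sorted) and `report`
#'   (per-sample counts by removal reason, including `retained`).
#' @export
filter_somatic <- function(variants, pon, healthy_calls, known_sites = list()) {
  if (nrow(variants) == 0L) {
    return(list(variants = variants,
                report = tibble(sample = character(), reason = character(), n = integer())))
  }
  pon_keys <- if (nrow(pon) > 0L) variant_key(pon) else character()
  healthy_keys <- unique(variant_key(as_call_table(healthy_calls)))
  if (is.data.frame(known_sites)) known_sites <- list(known = known_sites)
  known_keys <- unique(unlist(map(known_sites, variant_key))) %||% character()

  key <- variant_key(variants)
  reason <- case_when(
    key %in% pon_keys ~ "pon",
    key %in% healthy_keys ~ "healthy",
    key %in% known_keys ~ "known_sites",
    TRUE ~ "retained"
  )
  report <- tibble(sample = variants$sample, reason = reason) |>
    count(.data$sample, .data$reason, name = "n") |>
    arrange(.data$sample, .data$reason)
  list(variants = variant_sort(variants[reason == "retained", , drop = FALSE]),
       report = report)
}
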