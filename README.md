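# aidscope

Downstream analysis of somatic variant calls from tumor whole-exome
sequencing in B-cell lymphoma models where activation-induced deaminase
(AID) mutagenesis is unleashed by loss of uracil-N-glycosylase (UNG).

## The scientific problem

AID initiates somatic hypermutation by deaminating cytosine to uracil on
DNA, preferentially in **WRC/GYW** sequence context (W = A/T, R = A/G,
Y = C/T; the C of WRC and the G of GYW are the mutated bases — the same
motif read on the two strands). UNG normally excises these uracils; when
UNG is absent, replication over the U:G mismatch fixes **C:G transition**
mutations. Tumor exomes from such mice therefore carry an AID fingerprint:
an excess of C:G transitions, concentrated in hotspot motifs, and — when
AID is supra-expressed — a broader subclonal architecture (higher
intratumor heterogeneity, ITH) and a wider range of mutated cancer genes.

`aidscope` implements the complete downstream pipeline needed to measure
these effects in a two-genotype tumor cohort with one healthy-tissue
control, plus a seeded cohort simulator with full ground truth, so every
stage is testable without external data:

1. **Panel-of-normals (PON) filtering** (`build_pon()`, `filter_somatic()`).
   The PON is the union of three keyed sets: *set1*, the intersection of the
   germline-caller and somatic-caller calls on healthy tissue; *set2*,
   variants called in healthy tissue and in all `n_all` tumors, tolerating a
   NO_PASS caller label in at most 2 of them; *set3*, variants called in
   healthy tissue and in at least `n_most` tumors, PASS wherever called.
   Tumor variants are then removed if they hit the PON, the healthy-tissue
   calls, or a known-sites list (dbSNP-like / strain-variant-like).
2. **Mutation spectrum** (`classify_substitution()`, `is_hotspot()`,
   `target_composition()`, `spectrum_summary()`, `compare_spectra()`).
   Per-base mutation frequencies `f = m / N` where `m` counts C:G
   transitions (total, or within hotspot context) and `N` is the matching
   count of eligible target-space bases; groups are compared with
   chi-square (no continuity correction) or two-sided Fisher tests on the
   mutated/unmutated 2x2 tables.
3. **Clonal architecture and ITH** (`filter_for_clustering()`,
   `fit_vaf_clusters()`, `label_clonality()`, `compare_ith()`). Variants
   with >= 100 supporting reads, VAF <= 0.8 and outside CNV regions are
   clustered with a binomial mixture, `alt ~ Binomial(depth, p_j)`, fit by
   EM with BIC model selection. The cluster with the highest mean VAF is
   *clonal*; all others *subclonal*; the pooled subclonal proportion per
   genotype is compared with a two-sided Fisher test.
4. **Cancer-gene annotation** (`load_gene_sets()`, `annotate_cancer_genes()`,
   `exclusive_genes()`, `exclusive_spectrum()`). Presence/absence matrix
   over driver and lymphoma gene sets with per-gene most-severe-consequence
   reduction, genotype-exclusive gene detection, and the C/G vs A/T and
   hotspot-proportion contrasts on the exclusive genes.
5. **Cohort simulator** (`sim_config()`, `simulate_cohort()`,
   `emit_gene_annotations()`, `write_cohort()`). Two genotype presets
   ("WT-like" and "KI-like") differing in mutation load, hotspot weight and
   subclone structure; binomial read support on Poisson depths with
   expected VAF `purity * CCF / 2`; everything keyed by one seed.

All user-facing functions take and return tibbles, so stages chain with the
pipe; fitted objects have `tidy()`/`glance()` methods and `autoplot()`/
`plot_*()` figures.

## Worked example

`run_pipeline()` drives everything end-to-end from a YAML config
(simulation, serialization, re-loading through the format readers, and all
four analysis stages):

```r
library(aidscope)
cfg <- system.file("extdata", "demo_config.yaml", package = "aidscope")
res <- run_pipeline(cfg, out_dir = "demo_out")

dplyr::select(glance(res$spectrum),
              group, n_ts_cg, freq_ts_cg, freq_ts_cg_hotspot, enrichment_ratio)
#> # A tibble: 2 × 5
#>   group   n_ts_cg freq_ts_cg freq_ts_cg_hotspot enrichment_ratio
#>   <chr>     <int>      <dbl>              <dbl>            <dbl>
#> 1 ki_like     304    0.0181              0.0407             4.49
#> 2 wt_like     142    0.00845             0.0136             2.12

res$ith
#> <ith_test> pooled clonal/subclonal counts:
#>         clonal subclonal
#> wt_like    203        81
#> ki_like    241       228
#> subclonal proportions: wt_like = 0.285, ki_like = 0.486
#> two-sided Fisher p = 5.14e-08
```

The KI-like group (AID supra-expression) shows a higher C:G-transition
frequency, stronger focusing into WRC/GYW hotspots (per-base enrichment
ratio 4.49 vs 2.12 — the simulator's true site weights are 5 and 2), and a
higher pooled subclonal proportion (0.486 vs 0.285): the direction of every
headline effect the analysis is designed to detect. Per-tumor cluster
tables are available via `tidy(res$architectures$KI1)`, the gene matrix via
`res$gene_matrices`, and genotype-exclusive genes via `res$exclusive`.

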