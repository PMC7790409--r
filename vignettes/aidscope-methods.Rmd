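---
title: "Models and methods behind aidscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aidscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aidscope` analyses somatic variant calls from tumor exomes of UNG-deficient
B-cell lymphoma models, where AID-initiated cytosine deamination leaves a
characteristic footprint: C:G transition mutations focused in WRC/GYW
hotspot motifs, and — under AID supra-expression — a more subclonal tumor
architecture. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic cohort does and does not
emulate.

## Variant representation

Every stage exchanges a flat tibble with one row per called ALT allele per
sample: locus (`chrom`, 1-based `pos`), normalized alleles, read support
(`depth`, `alt_count`, `vaf = alt_count/depth`), the caller label collapsed
to `PASS`/`NO_PASS` (anything other than literal `PASS`, including `.`, is
`NO_PASS` — the filtering rules only ever distinguish these two), and
gene/consequence annotation. Depth and alt support are read from per-sample
`AD`/`DP` FORMAT fields first, with an INFO fallback; a record with neither
is an error rather than a silent zero, because the downstream VAF cutoff at
0.8 makes the VAF safety-critical. VCF positions are 1-based and BED
intervals 0-based half-open; all conversions live in the I/O module and
internal positions are 1-based throughout.

INDEL keys are normalized by parsimony trimming (shared suffix, then shared
prefix with a position shift). Full left-alignment against the reference is
not implemented: the simulator emits parsimonious alleles, and trimming is
sufficient for key identity across call files from the same aligner. This
is a known limitation for data mixing callers with different padding
conventions.

## Panel of normals and somatic filtering

The panel of normals is built from the cohort itself:

* **set1** — keys called by *both* the germline caller and the somatic
  caller on the healthy tissue;
* **set2** — keys called in the healthy tissue and in **all** `n_all`
  tumors, with a `NO_PASS` label in at most `max_no_pass_set2` (default 2)
  of them;
* **set3** — keys called in the healthy tissue and in at least `n_most`
  (default `n_all - 2`) tumors, labeled `PASS` in *every sample in which
  they were called*.

Two readings deserve a note. "Called in" a sample means present as a key
regardless of label — the set2 rule, which explicitly tolerates `NO_PASS`
labels, only makes sense under that reading. And set3's "PASS in all the
samples" is read as "PASS wherever called": requiring a call in literally
every sample would contradict the `>= n_most` recurrence threshold.
Membership in "healthy tissue" can be taken from the somatic calls, the
germline calls, or either (the default).

A tumor variant is then retained iff its key is absent from the PON, from
the healthy-tissue calls, and from every known-site list. Removal reasons
are assigned with the fixed precedence PON → healthy → known-sites so that
reports are deterministic when rules overlap.

## Hotspot motif and spectrum statistics

A reference C at position $p$ is a hotspot when positions $p-2,p-1$ match
W,R; a reference G when $p+1,p+2$ match Y,W — the reverse-complement
reading of the same motif, so classification is strand-symmetric by
construction. Hotspot status depends only on the reference, never on the
observed allele. The degeneracy sets default to the standard IUPAC
R = A/G, Y = C/T, W = A/T; R is configurable (`r_bases`) because a
nonstandard R = C/G variant circulates in print, and the 4-mer WRCY/RGYW
motif is available via `motif = "wrcy"`.

Motif context is read from the full reference chromosome; a capture-target
boundary does not truncate context, because the reference is available
beyond it. Positions whose context runs past a *chromosome* end are flagged
`edge` and never hotspot; they still count in the C/G denominator.

Per-base frequencies divide mutation counts by target-space base counts:
C:G transitions over all C/G bases ($n_{CG}$), or over hotspot C/G bases
($n_{CG,hot}$). Only C:G transitions enter the headline analysis — the
class produced by replication over unrepaired U:G mismatches; transversions
and A/T classes are tallied for spectrum-wide views. Group frequencies are
reported both as pooled counts over the common denominator (the headline,
since the chi-square comparison operates on pooled counts) and as the mean
of per-sample frequencies. Contrasts are 2x2 tables of mutated vs unmutated
eligible bases, tested with Pearson chi-square without continuity
correction, or the exact two-sided Fisher rule (sum over tables no more
probable than the one observed).

## Clonal architecture

Variants enter clustering only with `depth >= 100` (VAF estimate
stability), `vaf <= 0.8` (residual germline removal; such variants are
never labeled), and loci outside CNV regions (the model below assumes
copy-neutral diploid loci; CNV handling is exclusion, not VAF correction).

Read counts are modeled as a k-component binomial mixture,
$alt_i \sim \mathrm{Binomial}(depth_i, p_j)$ with weights $\pi_j$, fit by
EM for $k = 1..k_{max}$ (default 6) with 10 seeded k-means++-style restarts
per k, keeping the best likelihood; k is selected by BIC with $2k-1$
parameters. This is a deliberate simplification of the variational
beta-mixture clustering used by established subclone-inference tools such
as SciClone: the contract — clusters with mean VAFs feeding a
highest-VAF-is-clonal labeling rule — is preserved, while the model is
simple enough to admit exact parameter-recovery tests against simulated
ground truth. Components whose means differ by less than
`merge_tol = 0.02` are merged (weighted mean; ties in the clonal label are
thereby resolved before labeling). The EM asserts a non-decreasing
log-likelihood on every iteration; inputs are sorted internally so the fit
is invariant to input order given the seed; success probabilities are
clamped to $[10^{-6}, 1-10^{-6}]$.

The highest-mean cluster is labeled clonal, all others subclonal, and the
subclonal proportion (subclonal / clustered variants) is the ITH proxy.
Groups are compared by pooling clonal/subclonal counts over tumors into one
2x2 table tested two-sided by Fisher; per-tumor proportions are reported
without a test, since the group-level contrast is defined on pooled
counts.

## Cancer genes

Gene sets are plain-text lists, uppercased and deduplicated. The
presence/absence matrix covers genes in the driver/lymphoma union with at
least one retained variant; each (gene, tumor) cell keeps the most severe
consequence under an explicit, overridable order (least → most severe):
synonymous < UTR/non-coding < missense < inframe indel < splice <
stop-gained/nonsense < frameshift. An explicit order is used because
annotation tools version their own rankings and the reduction must be
deterministic. Genotype-exclusive genes are computed after an optional
recurrence filter (present in >= 2 tumors of a group) that suppresses
singleton genes.

The exclusive-gene spectrum contrast (C/G vs A/T proportions; hotspot vs
non-hotspot among C/G mutations) is tested two ways, because the choice
of null is genuinely open: against the target-space base
composition (same construction as the spectrum contrasts), and against the
other genotype's exclusive-gene variants. Both rows are labeled in the
output; neither is silently preferred.

## The synthetic cohort

The simulator generates the study conditions end-to-end: an i.i.d. random
reference (default 1 Mb, GC 0.42) targeted as one interval; 50 shared
germline variants (30% homozygous) present in every sample; 25 recurrent
artifact loci in all samples with per-sample `NO_PASS` labels (to exercise
PON sets 2/3); and per-tumor somatic mutations. Each somatic mutation draws
its class (C:G transition with probability `p_cg_transition`, the remaining
substitution classes uniform, and a configurable INDEL fraction of 0.24)
and its site — C/G sites carry relative weight `hotspot_w` when in hotspot
context, which makes the expected per-base enrichment ratio equal to `w`
itself, a closed-form oracle the tests check. Clone assignment gives each
mutation a cancer-cell fraction (clonal CCF 0.95, or a group-specific
subclone CCF), and read support is `depth ~ Poisson(mean_depth)`,
`alt ~ Binomial(depth, purity x CCF / 2)` — the copy-neutral diploid
expectation. CNV BEDs are emitted only to exercise the clustering exclusion
filter; no VAF distortion is modeled.

Two presets set the genotype contrast: WT-like (7 tumors, 450 mutations,
`p_cg_transition` 0.65, `w = 2`, one subclone at CCF 0.35 holding 25% of
mutations) and KI-like (8 tumors, 800 mutations, 0.80, `w = 5`, three
subclones at CCF 0.50/0.35/0.20 holding 50%). These presets encode the
qualitative genotype contrast the analysis is designed to detect — higher
load, stronger hotspot focusing and higher subclonality under AID
supra-expression — not any quantitative reference values.

Parameter conventions worth stating:

* `purity = 0.8` is a conventional tumor purity for solid lymphoid
  tumors; purity is rarely measured directly in such cohorts.
* `mean_depth = 150`: the clonality stage discards variants with fewer than
  100 supporting reads, so the simulator's per-variant support distribution
  must place most variants above that bar for clustering to be possible at
  all — as it evidently was in the original analysis, whose genome-wide
  *average* coverage (79x) reflects non-uniform capture coverage rather
  than the support of the analyzed variants. A Poisson mean of 150 puts
  ~99.9% of variants above 100 reads.
* The gene universe scales with the genome (one synthetic gene per 200 bp;
  5000 genes at the default 1 Mb) and the driver/lymphoma sets scale to 459
  and 239 genes, the sizes of the curated sets the analysis targets. The
  scaling preserves the sparsity that the exclusive-gene contrast depends
  on: most genes unmutated in any one tumor.

What the simulator does **not** emulate: read-level errors and mapping
artifacts, non-uniform capture coverage, copy-number effects on VAF,
mutational processes other than the single AID-like class mixture, linkage
between mutations, and clonal phylogenies beyond a flat clone/subclone
structure. Passing tests therefore demonstrate that the *computations* are
correct and that the direction-of-effect logic recovers known truth; they
do not validate caller behavior or alignment artifacts on real data.

## Problem sizes and determinism

The test suite runs the oracle comparisons at 100 random toy cohorts
(PON/filter set logic), 100 random kilobase sequences (hotspot scan), 2000
weighted site draws on a 100 kb reference across 50 seeds (enrichment), 25
seeded mixture fits each for the two- and three-cluster recovery checks,
and 50 seeded six-tumor cohorts for the ITH direction check — sizes chosen
so each property is measured with comfortable margins while the whole suite
stays quick on one CPU. Every random draw in the package flows through an
explicit seed (`withr::with_seed`); the end-to-end pipeline writes only
deterministic text (no timestamps), so identical config + seed yields
byte-identical output trees, which the suite asserts with file hashes.

## Known limitations

* Binomial clustering ignores overdispersion from subclonal copy-number or
  purity variation; a beta-binomial extension would be the next step for
  real data.
* Position-only matching for known-site lists is available but
  position+allele is the default; site lists with different normalization
  conventions should be normalized upstream.
* The exclusive-gene Fisher contrast remains ambiguous in the source
  material; both implemented baselines are reported rather than resolved.
* The simulator's uniform site model means target composition, not local
  chromatin or transcription, determines hotspot exposure.
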