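Package: aidscope
Title: AID Hypermutation Spectrum and Intratumor Heterogeneity from Tumor Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of somatic variant calls from tumor whole-exome
    sequencing in activation-induced deaminase (AID) driven, uracil-N-glycosylase
    (UNG) deficient B-cell lymphoma models. Builds a cohort-specific panel of
    normals from healthy-tissue and recurrent tumor calls and removes germline
    and artifact variants; classifies substitutions by transition/transversion
    and strand-aware WRC/GYW AID-hotspot context with target-space base
    denominators; infers per-tumor clonal architecture from variant allele
    frequencies with a binomial mixture model and labels clonal versus subclonal
    variants; annotates variants against cancer driver and lymphoma gene sets
    with most-severe-consequence reduction; and ships a seeded synthetic cohort
    simulator with full ground truth so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
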