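Package: panelvar
Title: Targeted Gene-Panel Variant Calling, Copy-Number Detection and
    ACMG Triage for Hereditary Hearing Loss
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a clinical targeted-sequencing pipeline for
    syndromic and non-syndromic sensorineural hearing loss: threshold-based
    SNV/indel calling from quality-filtered pileup evidence, per-target
    copy-number detection against a pooled background combining read depth and
    allelic imbalance, homology-aware flagging of variants in conflictive
    (pseudogene-shadowed) regions, minor-allele-frequency and ACMG/AMP
    combining-rules triage with tiered reporting and inheritance-consistency
    checking, cohort diagnostic-yield summarisation, and an analytical
    validation simulator that generates pileups, read-count matrices and truth
    sets with recorded seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    VariantAnnotation,
    GenomicRanges,
    IRanges,
    SummarizedExperiment
Config/testthat/edition: 3
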