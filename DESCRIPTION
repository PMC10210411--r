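Package: bcancestry
Title: Ancestry-Stratified Molecular Profiling of Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for ancestry-stratified molecular profiling of bulk tumor
    sequencing cohorts. Estimates per-patient continental admixture
    proportions from ancestry-informative markers by a supervised EM
    algorithm and classifies patients into African-ancestry and
    European-ancestry groups by threshold rules; compares pathogenic
    somatic-alteration carrier prevalence between groups with
    continuity-corrected chi-squared tests; performs batch-aware
    differential expression with a moderated t-statistic combined across
    assay batches by weighted-Fisher (wFisher) p-value meta-analysis and
    sample-size-weighted fold-change averaging; and scores single-sample
    gene-set enrichment (ssGSEA) with group comparison. Includes a
    synthetic-cohort generator (Balding-Nichols reference panels, admixed
    genotypes, clinical tables, mutation matrices, and negative-binomial
    counts with batch effects) so every stage of the pipeline can be
    exercised end to end without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
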