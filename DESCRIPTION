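Package: vdmomics
Title: Multi-Omics Functional Attribution for Gene-Based GWAS of Verbal
    Declarative Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attributes function to multi-cohort genome-wide association
    results for verbal declarative memory. Converts per-cohort variant-level
    summary statistics into gene-level association scores (greedy linkage
    disequilibrium clumping, Simes combination p-value, rank uniform score),
    meta-analyzes variants (sample-size weighted Z) and genes (binomial count
    test) across cohorts, relates association strength to multi-omics
    annotations (eQTL/meQTL linkage disequilibrium, tissue expression,
    transcription factor and microRNA regulons, immune annotation) through
    permutation-calibrated logistic regression, performs uniform-score
    gene-set enrichment with two cross-cohort meta-analysis approaches, and
    tests pathway component genes for differential expression across ordered
    cognitive-status groups with a mean-rank permutation set test. A
    synthetic-data generator emulates multi-cohort summary statistics with
    block linkage disequilibrium, planted gene and pathway effects, planted
    annotation enrichment, and group-shifted expression matrices so the whole
    pipeline is testable without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    metafor,
    limma,
    fgsea,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
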