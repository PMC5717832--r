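Package: poolscreen
Title: Pooled DNA Sequencing Screens: Design, Allele-Count Calling,
    Carrier Decoding and Rare-Variant Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control rare-variant screens that sequence DNA
    pools instead of individuals. Builds phenotype-homogeneous pools and
    orthogonal validation pools with bounded pairwise overlap, estimates
    per-pool allele counts from read data with a binomial error model,
    runs coverage quality control, decodes the carriers of rare variants
    across overlapping pool stages by parsimonious search, applies
    functional-class and rarity filters against a registry of previously
    reported pathogenic variants in monogenic diabetes genes, and computes
    carrier-level odds ratios, Woolf confidence intervals, Fisher exact
    tests and permutation gene-burden tests. A synthetic-cohort generator
    reproduces the statistical structure of such screens (rare-variant
    site frequency spectra dominated by singletons, deep pooled coverage,
    sequencing error, pathogenic enrichment at configurable odds ratios)
    so the whole pipeline can be exercised end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
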