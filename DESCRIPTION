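Package: ctcna
Title: Single-Cell Copy-Number Aberration Analysis for Circulating Tumor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for copy-number aberration (CNA)
    analysis of single circulating tumor cells (CTCs) profiled by low-pass
    whole-genome sequencing. Provides a seeded simulator of single-cell
    bin-count cohorts with known ground-truth CNAs, per-cell CNA calling
    (median normalization, penalized change-point segmentation, integer
    copy-number assignment and a dual Mann-Whitney/Kolmogorov-Smirnov
    significance filter), Jaccard-index genomic-imbalance scoring of CTCs
    against reference leukocytes with non-parametric group comparisons,
    stratified recurrence counting over focal cytogenetic regions and genes,
    and hypergeometric gene-set enrichment with construction of a
    shared-gene term network.
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
    grDevices,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
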