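Package: cellgwas
Title: GWAS Marker-Set Enrichment and Cell-State Scoring for Single-Cell
    Immune Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping complex-trait GWAS signal onto gene sets
    derived from single-cell transcriptomics, built around a sum-based
    marker-set statistic (the sum of squared single-marker effects over
    markers inside 20-kb gene windows) tested against an LD-preserving
    cyclical-permutation null with empirical p-values and
    Benjamini-Hochberg FDR across a trait-by-set grid. Also implements
    cell-cycle proliferation indices from G1/S and G2/M gene panels,
    scaled module scoring of LPS-response gene programs over a treatment
    time course with qualitative trajectory classification, pseudocell
    aggregation for co-expression preprocessing, and seeded synthetic
    generators for GWAS summary statistics and single-cell count
    matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
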