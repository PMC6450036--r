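Package: markercall
Title: Marker-Based Cell-Type Annotation for Single-Cell RNA-Seq Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates cell clusters in single-cell RNA-seq count matrices
    with cell types using a curated marker-gene compendium. Scores each
    cluster against every cell type with a frequency-weighted cell-type
    activity (CTA) statistic, assesses marker overlap with a one-sided
    hypergeometric test under Benjamini-Hochberg control, and falls back to
    an "Unknown" label when no call is significant. Also provides the
    surrounding toolkit: count-matrix quality control (library-depth,
    doublet-score and cluster-size filters), library-size normalization,
    per-cluster median expression profiles, gene-set activity enrichment
    with Bonferroni control, motif-support (regulon) enrichment via
    recovery-curve AUCs with kernel-density tail significance, a boolean
    gene-search interface over cluster profiles, and seeded synthetic-data
    generators with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
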