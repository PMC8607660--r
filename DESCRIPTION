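Package: scwgd
Title: Single-Cell Co-Expression Analysis of Whole-Genome-Duplication Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting functional redundancy between
    whole-genome-duplication (WGD) derived paralog pairs from droplet
    single-cell RNA-seq of plant vascular tissue. Provides readers for the
    10x-style MatrixMarket bundle, gene- and cell-level quality-control
    filters, per-cell log-normalization, cluster-enriched and
    cluster-specific marker calling (Wilcoxon rank-sum with expression
    prevalence and natural-log fold-change thresholds), binarized Jaccard
    co-expression with a prevalence filter, paralog-versus-background
    signed-rank comparisons, per-cluster expression-overlap profiling and
    redundancy-candidate classification, Nei-Gojobori (1986) dN/dS
    estimation for aligned coding sequences, one-sided Fisher term
    enrichment with Benjamini-Hochberg adjustment, and a synthetic-atlas
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
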