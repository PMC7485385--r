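Package: panelmiR
Title: Detection Filtering, Global-Mean Normalization and Downstream
    Analysis of High-Throughput qPCR miRNA Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for high-density qPCR (OpenArray-style)
    miRNA profiling experiments. Implements joint detection filtering of
    cycle-threshold (Ct) matrices, global-mean and reference-gene delta-Ct
    normalization with 2^-ddCt relative quantification, fold-change based
    classification of regulated miRNAs between genotype-by-treatment
    groups, Venn partitioning of regulated sets across comparisons,
    integration of validated and predicted miRNA-target tables with
    per-source score rescaling, hypergeometric over-representation
    analysis with Benjamini-Hochberg correction, summary-statistics
    t-tests and one-way ANOVA with Fisher's protected LSD, and a
    synthetic-data generator with ground-truth tables for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
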