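Package: ternaryDE
Title: Factorial Single-Channel Microarray Analysis with Ternary
    Expression-Pattern Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of 2x2 factorial (genotype x treatment)
    single-channel microarray experiments: normexp background correction,
    quantile normalization, expression filtering against per-array
    background estimates, gene-wise linear modelling with empirical-Bayes
    variance moderation and moderated t-statistics, Benjamini-Hochberg
    FDR control, ternary (induced/repressed/unaffected) state calls over
    four canonical contrasts, exhaustive contrast-pattern clustering with
    a priming/attenuation taxonomy, Fisher-exact functional-category
    over-representation on hierarchical MapMan-style bins, delta-delta-Ct
    qPCR validation arithmetic and metabolite-ratio summaries. Includes a
    synthetic-data generator with planted ground truth for recovery and
    calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    withr,
    testthat (>= 3.0.0),
    limma,
    jsonlite
biocViews: Microarray, DifferentialExpression, GeneExpression,
    Normalization, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
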