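Package: sigpop
Title: Signature-Positive Cell Population Analysis for Single-Cell and Bulk Transcriptomics
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies and characterizes gene-signature-positive cell
    subpopulations in single-cell RNA-seq data. Provides a negative-binomial
    UMI count simulator with planted signature-positive cells, Seurat-style
    quality control, log-normalization, gene-wise scaling, permutation-based
    principal-component selection and graph clustering, per-cell z-scored
    signature scoring with ROC-AUC cluster enrichment calls (AUC > 0.7,
    Wilcoxon rank-sum p < 0.01), positive/negative cell classification,
    cluster differential expression and derivation of custom population
    signatures, signature-signature Pearson correlation with strength
    banding, cross-condition abundance-shift testing, and bulk-cohort
    interrogation by tumor-level scoring, chi-squared grade association and
    Kaplan-Meier/log-rank relapse-free survival comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
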