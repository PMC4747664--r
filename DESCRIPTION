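Package: exprDiversity
Title: Simpson's Diversity Index for Gene Expression in Tumor and Normal
    Samples
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies how evenly a sample distributes its transcriptional
    output across genes with the Simpson's diversity index for gene
    expression (SDIG), and compares tumor against non-tumor cohorts via
    positive-pair statistics (PPS, PPPN/PNPN) and a one-sided Welch t-test.
    Includes the full preprocessing stage for two-channel cDNA microarray
    spot tables (background correction, flag and 1.5x-background filtering,
    reference-ratio or paired-channel expression, replicate filtering,
    mean imputation), readers for expression matrices and the GEO
    series-matrix dialect, a seeded Dirichlet simulator for
    evenness-controlled synthetic cohorts, and an end-to-end pipeline
    producing per-sample diversity tables, cohort summary rows and
    boxplot-style five-number summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
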