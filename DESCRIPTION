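Package: countpower
Title: Power-Aware Differential Expression Analysis for RNA-seq Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical power analysis and power-informed differential
    expression for bulk RNA-seq count matrices. Implements a closed-form
    negative-binomial power model driven by sequencing depth and the
    biological coefficient of variation, an FDR-adjusted per-test
    significance level for gene-wise detectability, TMM normalization and
    CPM-based expression filtering, common and tagwise dispersion
    estimation, exact-test and quasi-likelihood GLM differential
    expression with Benjamini-Hochberg correction, triage of
    non-significant genes into detectable and non-detectable classes,
    signature construction combining confident positives and confident
    negatives, exploratory analytics (correlation, hierarchical
    clustering, PCA, t-SNE), and a negative-binomial simulator with known
    truth for Monte-Carlo validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
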