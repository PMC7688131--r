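Package: ras6m
Title: Six-Model Dose-Response Fitting and Expression-Based
    Drug-Sensitivity Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for discovering and validating gene-expression biomarkers
    of chemosensitivity, built around the 6-model (6M) approach to
    dose-response analysis: six constrained variants of the four-parameter
    logistic curve are fitted to cytotoxicity data and the fit with the
    lowest residual standard error is selected, from which IC50, IC90,
    IC95, EC50, Amax and Activity Area are derived. Around the curve
    machinery the package provides variance/mean/range probe filtering and
    probeset-to-gene collapsing for microarray matrices, exhaustive
    best-subsets linear regression of IC50 on gene expression with repeated
    discovery/test cross-validation, log-rank-with-multiple-cutoffs (LRMC)
    survival cutpoint scanning with Kaplan-Meier, log-rank and binary Cox
    summaries, a combined three-gene prognostic classifier, delta-delta-Ct
    relative quantification for qRT-PCR, and seeded synthetic-data
    generators that emulate the statistical structure of cell-line
    cytotoxicity screens, expression cohorts and survival cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
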