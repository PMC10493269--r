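Package: wellridge
Title: Balanced-Bootstrap Ridge Regression for Repeated Cross-Sectional
    Well-Being Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate predictors of mental well-being from
    repeated cross-sectional surveys with strongly imbalanced arrival
    counts over time. Implements balanced down-sampling bootstrap over
    survey weeks, cross-validated L2 (ridge) regression with main
    effects and first-order time interactions, and percentile-based
    coefficient inference, together with a synthetic survey generator
    with known injected effects for validation. Includes scoring for
    the 14-item Warwick-Edinburgh Mental Well-Being Scale (WEMWBS),
    near-zero-variance and correlation predictor filters, descriptive
    week-by-week summary tables, and ggplot2 visualisations of
    bootstrap coefficient distributions.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
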