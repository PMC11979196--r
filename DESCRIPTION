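Package: cgfiboot
Title: Corrected Goodness-of-Fit Index and Bootstrap Fit Evaluation for
    Confirmatory Factor Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits confirmatory factor analysis (CFA) models to continuous
    (covariance/maximum likelihood) or ordered-categorical (polychoric
    correlation, unweighted/diagonally weighted/full weighted least squares)
    data and evaluates model fit with the classic descriptive index battery
    (chi-square, CFI, TLI, GFI, AGFI, RMSEA, SRMR, AIC, BIC) plus the
    corrected goodness-of-fit index (CGFI), a small-sample and
    model-complexity correction of the GFI. Sampling uncertainty of every
    index is characterized by a non-parametric case-resampling bootstrap
    with percentile 95% confidence intervals. Includes a synthetic
    factor-model data generator (multivariate normal and its ordinal
    discretization) and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
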