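Package: geomgof
Title: Goodness-of-Fit Tests for the Geometric Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Watson and Anderson-Darling goodness-of-fit tests for the
    geometric distribution with estimated success probability. Implements the
    cumulative-deviation test statistics, the asymptotic null distribution via
    eigenvalues of the MLE-corrected covariance quadratic form, upper-tail
    probabilities and quantiles of weighted chi-square sums by characteristic
    function inversion, regeneration of asymptotic critical-value tables,
    Monte Carlo finite-sample percentage points, and extraction of run lengths
    from numeric time series (e.g. daily price runs of financial indices).
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
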