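Package: pdtest
Title: Permutation Distancing Test for Autocorrelated Single-Case AB-Phase Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric evaluation of treatment effects in single-case
    observational AB-phase time series with serial dependency. Implements the
    permutation distancing test, which controls lag-one autocorrelation by
    down-sampling the equidistant series into subsets of observations spaced k
    time steps apart and gating the distance on Ljung-Box diagnostics, together
    with the traditional permutation test and the single-case randomization
    test over intervention start points. Includes equidistance preprocessing
    (missing time markers, duplicate markers), per-phase trend inspection and
    detrending, phase plots, and a Monte Carlo framework based on an AR(1)
    interrupted time-series generator for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
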