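Package: privchisq
Title: Differentially Private Chi-Squared Tests of Independence for Small Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for releasing chi-squared tests of independence on I x J
    contingency tables under epsilon-differential privacy when samples are
    scarce. Implements the RandChiDist mechanism: a tight global-sensitivity
    formula for the chi-squared statistic when row totals are public, the
    Laplace-convolved null distribution used to calibrate rejection thresholds
    and private p-values, and baseline mechanisms (RandChi, RandCell, a
    Monte-Carlo independence test, and the classical non-private test). Also
    provides a brute-force sensitivity oracle over the neighboring-table
    relation, a multinomial simulation harness for empirical significance and
    power experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
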