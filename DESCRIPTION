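Package: roctrio
Title: Parametric, Nonparametric and Semiparametric ROC Curve Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the ROC curve and its area for a continuous diagnostic
    test with three methods: the parametric binormal model with delta-method
    standard errors, the empirical Mann-Whitney estimator with a tie-corrected
    variance, and a semiparametric probit regression of pairwise
    placement-value indicators with stratified bootstrap inference. Includes a
    Monte-Carlo benchmarking engine that compares the bias, standard errors,
    root mean square errors and confidence intervals of the three estimators
    under normal, lognormal (skewed) and uniform (monotone) test-result
    distributions, plus a reporting path for user-supplied biomarker data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
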