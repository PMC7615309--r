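Package: colliderMI
Title: Collider Bias from Auxiliary Variables in Multiple Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the bias and standard error of the
    multiple-imputation (MI) estimator when a collider is used as an
    auxiliary variable in the imputation model. Represents linear-Gaussian
    path models (directed acyclic graphs) and computes their implied joint
    and conditional moments exactly; implements closed-form expressions for
    the maximum M-bias of the MI estimator when the outcome or the exposure
    is partially observed, standard-error profiles of the MI and
    complete-records estimators, and the logit-to-probit odds-ratio
    conversion; provides a proper normal-linear MI engine with Rubin's
    rules pooling, a probit-threshold missingness simulator, Monte-Carlo
    sweep designs over the missingness proportion and the path
    coefficients, and an applied two-step workflow that screens candidate
    auxiliary variables for collider signatures and computes a plug-in
    maximum bias with an approximate confidence interval from summary
    statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
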