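Package: quickSDT
Title: Bayesian Adaptive Estimation of Signal-Detection Sensitivity Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a family of Bayesian adaptive psychophysical methods
    (qYN, qYNC, qYNR, qFC) that estimate the sensitivity threshold -- the
    signal intensity at which d-prime equals 1 -- in Yes-No, cued, rated and
    two-interval forced-choice detection tasks. The methods combine a
    signal-detection-theory model of the empirical psychometric function with
    grid-based Bayesian inference and one-step-ahead minimum-expected-entropy
    stimulus selection, so that sensitivity is estimated jointly with, and
    free of, decision-criterion confounds. Includes simulated observers and a
    Monte-Carlo study harness for accuracy/precision evaluation, and a
    maximum-likelihood fitter for method-of-constant-stimuli count data with
    parametric-bootstrap goodness-of-fit and standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
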