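Package: clustpred
Title: Performance of Standard and Random-Intercept Logistic Prediction Models in Clustered Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation framework comparing standard logistic regression with
    random-intercept (multilevel) logistic regression for clinical risk
    prediction when patients are clustered within centers or physicians.
    Generates clustered source populations with a latent normal center effect
    set by a target intraclass correlation, draws two-stage study samples,
    fits both models, computes predicted risks three ways (standard, marginal,
    conditional), and evaluates overall and within-cluster discrimination
    (Harrell's c-index) and calibration (calibration-in-the-large and
    calibration slope, including mixed-effect within-cluster versions) across
    Monte-Carlo replications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
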