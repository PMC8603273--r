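Package: sbpcourse
Title: Reference Systolic Blood Pressure Course Deviation Modelling After
    Stroke Thrombectomy
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the systolic blood pressure (SBP) course over the first
    24 hours after endovascular thrombectomy (EVT) as a polynomial
    mixed-effects "reference course" fit on patients with a favourable
    outcome, projects every patient's deviation from that course with
    empirical best linear unbiased predictors (EBLUPs), and relates those
    deviations to binary clinical outcomes through logistic regression
    with full-pipeline bootstrap confidence intervals and ROC/AUC
    stability evaluation over truncated monitoring windows. Includes a
    synthetic-cohort generator emulating the post-EVT monitoring protocol
    (irregular sampling, optional measurements, dropout) so the whole
    pipeline is testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
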