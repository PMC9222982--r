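Package: roicox
Title: Time-to-Event Prediction Incorporating Compatible Related Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cox proportional hazards modelling that exploits a compatible
    related (auxiliary) clinical outcome during training to improve
    prediction of a primary time-to-event outcome. Implements the
    L2-regularized linear Cox baseline, a joint weighted partial-likelihood
    model over primary and auxiliary outcomes with a shared bias, deep Cox
    variants with a multilayer feature extractor, Harrell's concordance
    index with the censored-earlier-pair discard rule, a stratified
    cross-validation harness, an exact one-sided Wilcoxon signed-rank model
    comparison, and an exponential Cox synthetic-data generator with
    correlated coefficient vectors and administrative censoring. The
    auxiliary outcome is consumed only while fitting; prediction for new
    patients never requires it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
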