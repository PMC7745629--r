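Package: ritmap
Title: Anatomically Restricted CNN Regression and Occlusion Mapping for
    Retinal OCT Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("ritmap", "developers", email = "ritmap@example.org",
           role = c("aut", "cre"))
Description: Simulates layered-retina OCT B-scan phantom cohorts with a
    known localized outer-retinal biomarker and continuous rod intercept
    time (RIT) labels, trains small convolutional neural network
    regressors on anatomically restricted B-scan windows across a grid of
    retinal eccentricities, and localizes the imaging features driving
    the predictions with signed mean-occlusion perturbation maps.
    Includes a patient-level cohort splitter, a Nesterov-Adam trainer
    with per-session best-validation-epoch model selection, nine-model
    ensemble inference, eccentricity-resolved error curves with
    confidence intervals, occlusion sensitivity variants, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
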