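Package: adaptivepe
Title: Adaptive Prediction-Error Coding: Task Simulation, Reinforcement-Learning Model Fitting, and Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a rewarded prediction task in which rewards are drawn
    from pseudo-Gaussian distributions crossing reward variability (SD of
    5, 10 or 15 GBP) with expected value (35 or 65 GBP), and implements four
    trial-by-trial reinforcement-learning models of behaviour on that task:
    Rescorla-Wagner with a single learning rate, Rescorla-Wagner with
    separate rates for positive and negative prediction errors, a
    Pearce-Hall model with a dynamic learning rate, and an adaptive
    Pearce-Hall model that scales prediction errors by the log-variability
    of the reward distribution. Provides maximum-likelihood fitting with a
    profiled Gaussian observation noise, multi-start bounded optimisation,
    a brute-force grid oracle, and AIC/BIC model comparison; behavioural
    outcome measures (performance error, scaler contingency tables,
    covariate residualisation, parametric and nonparametric group tests);
    and a trial-level analogue of the fMRI adaptive-coding analysis:
    synthetic ROI responses, prediction-error slopes per variability
    condition and error sign with serial orthogonalisation, and the
    inverse-SD weighted adaptive-coding contrast with rank-based group
    comparison. A single driver runs the full synthetic study end to end
    with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lhs,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
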