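Package: subpoisson
Title: Sub-Poissonian mRNA Noise: Moment Analysis, Stochastic Simulation,
    smFISH Estimators and ABC Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing ultralow (sub-Poissonian) intrinsic noise in
    constitutive gene expression. Implements a multi-step model of
    transcription with a cycling promoter, nuclear export and multi-step
    cytoplasmic mRNA degradation; computes exact steady-state means,
    variances and nuclear-cytoplasmic covariances from the linear moment
    equations; simulates the model exactly with the Gillespie stochastic
    simulation algorithm; estimates noise from single-molecule FISH spot
    tables (spot, intensity and hybrid counting, size-corrected and
    sliding-window Fano factors, nascent-transcript classification); fits
    model parameters by approximate Bayesian computation (ABC) rejection
    sampling with model selection over the number of rate-limiting steps;
    and generates ground-truthed synthetic smFISH datasets for estimator
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    rlang,
    tibble,
    tidyr,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
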