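Package: beliefupdatr
Title: Trial-by-Trial Models of Belief Updating Under Normative Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, fitting and comparison of trial-by-trial learning
    models for belief-rating tasks in which participants rate statements on a
    Likert scale and receive normative feedback. Implements five candidate
    models, including similarity-based prediction-error propagation anchored
    to initial beliefs, subject-level MAP estimation with Laplace
    approximation of model evidence, hierarchical Bayesian model comparison
    with protected exceedance probabilities, and a validation suite
    (parameter recovery, model-recovery confusion matrices, posterior
    predictive checks, prediction-error trend tests). A synthetic-cohort
    generator with latent-factor similarity structure stands in for human
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
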