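Package: qaopdnt
Title: Bayesian Hierarchical Modelling of a Quantitative Adverse Outcome
    Pathway for Developmental Neurotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies a simplified adverse outcome pathway (AOP) for
    developmental neurotoxicity (DNT) with a single nested, partially
    pooled Bayesian hierarchical logistic model.  Per compound, the model
    predicts the probability of inducing three common key events
    (reduction of BDNF, decrease of synaptogenesis, decrease of neural
    network formation) and the adverse outcome, chaining the key events
    along a directed acyclic graph.  Missing predictors are imputed
    during inference; missing key-event labels are handled by
    marginalization with posterior-predictive imputation.  Includes a
    built-in No-U-Turn sampler with divergence reporting, convergence
    diagnostics (rank-normalized split R-hat, effective sample size,
    Monte Carlo standard error), model-comparison metrics (PSIS-LOO,
    WAIC, Brier score), hyperprior sensitivity analysis, two-threshold
    low/medium/high hazard classification, confusion-matrix performance
    metrics, and a synthetic-data generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    withr,
    optparse
Config/testthat/edition: 3
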