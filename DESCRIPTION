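Package: flupk
Title: Population Pharmacokinetics of Fludarabine Lymphodepletion Before CAR-T Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of fludarabine
    (f-ara-A) given as lymphodepleting chemotherapy before CAR T-cell
    infusion. Implements a three-compartment disposition model with
    zero-order infusion input solved analytically, a covariate model with
    allometric body-weight scaling and a renal/non-renal clearance split,
    log-normal between-subject variability, Laplace (FOCE-type) marginal
    likelihood estimation with empirical-Bayes individual estimates and
    shrinkage, stepwise covariate selection by likelihood-ratio testing,
    goodness-of-fit residuals and prediction-corrected visual predictive
    checks, virtual-cohort simulation reproducing the study design, and
    exposure-targeted (AUC) dose individualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    readr,
    stats,
    numDeriv,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
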