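Package: jbpomdp
Title: Belief-State POMDP Modelling of Go/Stay Judgement-Bias Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a belief-state partially observable Markov decision process
    (POMDP) to choices and discretised reaction times from a go/stay
    judgement-bias task with fluctuating monetary stakes.  The model couples
    evidence accumulation over a random-dot stimulus with a gamma-hazard
    account of noisy interval timing, and lets the decision bias drift with
    within-task experience (average earning rate, weighted prediction errors,
    previous outcome) via Rescorla-Wagner dynamics.  Includes maximum-likelihood
    estimation with multistart, stepwise AIC/BIC model selection, a parameter
    recovery harness, sign-flip permutation tests, and mixed-model analyses
    linking fitted parameters and within-task experience to self-reported
    affect.  A synthetic-data generator reproduces the task structure
    (coherence schedule, sine-modulated stakes, affect-grid probes) so the
    full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    nlme,
    minqa,
    lhs,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
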