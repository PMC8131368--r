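Package: ewalearn
Title: Hierarchical Experience-Weighted Attraction Models for Social Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing socially transmitted behavioural techniques in
    open-diffusion experiments with experience-weighted attraction (EWA) models.
    Builds dynamic social-information windows from time-stamped observation
    logs, evaluates the forward EWA learning model (attraction updating,
    multinomial logistic choice, and a convex combination of individual and
    social choice), fits eight hierarchical Bayesian learning-strategy variants
    (individual learning, frequency dependence, and payoff-, rank-, kin-,
    female- and same-sex-biased transmission, plus a global model) by adaptive
    Markov chain Monte Carlo, compares them by the widely applicable
    information criterion (WAIC), and simulates open-diffusion datasets with
    known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
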