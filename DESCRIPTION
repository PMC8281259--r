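Package: cardiolpn
Title: Lumped-Parameter Circulation Modelling and Bayesian Assimilation for
    Secondary Pulmonary Hypertension
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-loop zero-dimensional (lumped-parameter) model of the
    adult heart and circulation with four elastance-based chambers, an aortic
    capacitor, a systemic RCR compartment and a pulmonary RC compartment.
    Provides Bayesian assimilation of sparse clinical targets (Gaussian
    likelihood, uniform box priors, repeated Nelder-Mead MAP estimation and
    differential-evolution adaptive Metropolis MCMC with Gelman-Rubin
    diagnostics), local sensitivity and Fisher-information identifiability
    analysis, pulmonary-pressure prediction from pulmonary-blind training,
    greedy ranking of clinical targets, and naive-Bayes detection of
    pulmonary hypertension with missing-data imputation and class-balancing
    strategies. Includes a synthetic-cohort generator emulating the noise and
    missingness structure of clinical EHR tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
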