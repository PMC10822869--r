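Package: dopfer
Title: Bayesian Trial-Level Models of Dynamic Facial Emotion Recognition
    Under Differential Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing trial-level accuracy in dynamic
    emotional-facial-expression recognition tasks comparing differential
    (DOP) and non-differential (NOP) outcome procedures. Implements a
    Bayesian binomial generalized linear model with a logit link,
    condition-indexed intercepts and nonlinear reaction-time and
    learning-curve covariates, optional schizotypy (SPQ) direct and
    moderation effects, adaptive Hamiltonian Monte Carlo sampling with
    Gelman-Rubin diagnostics, highest-density-interval plus
    region-of-practical-equivalence (HDI+ROPE) decision rules, posterior
    contrasts and summary tables, SPQ three-factor scoring with Cronbach's
    alpha, and a synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
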