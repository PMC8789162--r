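Package: dynOED
Title: Robust D-Optimal Design of Dynamic Gas-Exchange Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and estimation tools for dynamic respiration
    and fermentation experiments on stored fruit. Implements forward
    sensitivity analysis of the flow-through and closed-jar gas-exchange
    model, Fisher information matrices with a heteroscedastic measurement
    noise model, locally optimal and robust (pseudo-Bayesian) D-optimal
    design of piecewise-constant input profiles via low-discrepancy
    multistart optimization, sigma-point summaries of parameter uncertainty,
    maximum-likelihood fitting and Markov chain Monte Carlo posterior
    sampling, and a synthetic posterior-chain generator for fully
    reproducible desk-scale studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lhs,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
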