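Package: embedstable
Title: Designing Multistable Gene-Regulatory Models by Embedding Bistable Subsystems
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for constructing gene-regulatory network models with three or
    more stable steady states by embedding bistable two-gene subsystems through
    auxiliary-variable substitution. Implements Shea-Ackers double-negative
    feedback models without high cooperativity, closed-form and multistart
    numerical equilibrium analysis with Jacobian stability classification,
    random-parameter bistability screening with perturbation robustness tests,
    approximate Bayesian computation (rejection) parameter estimation, and
    Ito stochastic differential equation simulation of the GATA1-GATA2-PU.1
    haematopoietic fate-decision module with semi-implicit Euler integration,
    endpoint-state classification, and parameter-sweep ensemble analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
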