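Package: humoralsim
Title: Agent-Based Stochastic Simulation of the Humoral Adaptive Immune Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulator of the humoral adaptive immune
    response on discrete shape-space lattices. B and T helper cells are tracked
    individually with receptor coordinates on peptide/antigen lattices; self
    cells, foreign antigens, antibodies, danger signals and interleukins are
    counted populations. Events (births, deaths, selection, interactions,
    divisions) fire in a continuous-time exponential race with logistic
    throttling of birth rates. Two model presets are provided: a self-centered
    model in which positively selected regulatory T helper cells maintain a
    homeostatic image of self through weak, intermediate and strong interaction
    regimes, and a conventional model with negative selection and strong
    interactions only. Includes an experiment harness for repeated-infection
    immune memory, model-versus-model infection survival grids with one-sided
    Fisher exact tests, and uniform-sampling sensitivity analysis with Pearson
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
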