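Package: lvfix
Title: Fixation Probabilities in Stochastic Lotka-Volterra Competition Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the fixation probability of a mutant type in a
    resident population whose size fluctuates stochastically. Implements the
    two-type competitive Lotka-Volterra reaction system (birth, death and
    pairwise competition events) with exact Gillespie simulation, the
    weak-selection first-order approximation of the mutant fixation
    probability built on a population-size-dependent amplitude function
    solving a second-order linear boundary-value ODE, Euler-Maruyama
    simulation of the diffusion approximation, scale-function hitting
    probabilities for one-dimensional diffusions including the
    center-manifold projected model, and classical comparison formulas from
    the population-genetics literature (Otto-Whitlock, Kimura-Ohta,
    Uecker-Hermisson) with the parameter translations appropriate for this
    model. Includes a command-line interface and preset experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
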