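Package: avapk
Title: Population Pharmacokinetics of Apovincaminic Acid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modeling and simulation toolkit for the population pharmacokinetics
    of apovincaminic acid (AVA), the active metabolite of vinpocetine. Implements
    the closed-form two-compartment disposition model with zero-order absorption
    and lag time, a hierarchical population layer with formulation covariates,
    lognormal inter-individual variability and proportional residual error, a
    stochastic approximation EM (SAEM) estimator with importance-sampling
    likelihood, empirical Bayes estimates and model-selection criteria,
    goodness-of-fit and visual predictive check diagnostics, and replicate-trial
    simulation of dosing regimens with parameter uncertainty. A synthetic-data
    generator emulates the single-dose, three-formulation crossover study in
    healthy volunteers that underlies the model, so the full workflow is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ggplot2,
    withr
Config/testthat/edition: 3
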