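Package: dalbapk
Title: Population Pharmacokinetics and Exposure Simulation of Dalbavancin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic/pharmacodynamic analysis of
    dalbavancin, a long-acting lipoglycopeptide dosed at weekly intervals.
    Provides closed-form multi-dose infusion solutions for linear mammillary
    compartment models, a nonlinear mixed-effects fitting routine (Laplace
    approximation) with covariate screening and model-selection utilities,
    simulation-based diagnostics (visual predictive checks and normalized
    prediction distribution errors), Monte Carlo probability-of-target-
    attainment simulation stratified by renal function, and rules for timing
    therapeutic drug monitoring. Includes a synthetic-cohort generator that
    emulates sparse therapeutic-drug-monitoring study designs with known
    ground truth for validating the estimation machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
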