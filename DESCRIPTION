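Package: dlgrowth
Title: Diffusion-Limited Tumor Growth Laws for Preclinical PK/PD Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic, diffusion-limited tumor growth modelling for
    preclinical (xenograft) drug studies. Implements a spherical
    nutrient-diffusion growth law whose growing fraction is determined
    algebraically from tumor volume, an exponential plasma pharmacokinetic
    driver for the kill term, a quasi-steady reaction-diffusion extension for
    spatially limited drug penetration, the classical empirical comparator
    growth laws (linear, exponential, logistic, Gompertz, exponential-linear,
    surface growth, proliferative rim), nonlinear mixed-effects population
    estimation by stochastic approximation EM (SAEM) with importance-sampling
    likelihood and AIC, visual predictive checks, and a synthetic-cohort
    generator emulating cell-derived-xenograft study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
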