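Package: spatburst
Title: Spatial Stochastic Modelling of Bursty Nuclear Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a spatial stochastic model of nuclear mRNA with
    two-state (telegraph) transcription. Observations of the model form a
    spatial Cox process whose intensity solves a stochastically switching
    reaction-diffusion equation. The package provides closed-form and
    series moments for the one-dimensional model with absorbing, Robin
    (semi-absorbing) or reflecting nuclear boundaries, a Poisson-beta
    approximation of the molecular count distribution with spatially
    derived parameters, an exact-promoter particle-based stochastic
    simulator (1D and 2D, heterogeneous diffusivity), a steady-state
    finite-difference solver for irregular two-dimensional nuclei, and
    approximate Cox-process likelihood inference with profile-likelihood
    identifiability analysis over heterogeneous cell populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
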