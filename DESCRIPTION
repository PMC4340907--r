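Package: gridnet
Title: Noise Correlations and Kinetic Ising Functional Connectivity for Grid-Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing simultaneously recorded populations of
    medial entorhinal grid cells. Computes trajectory-conditioned noise
    correlations (spatially binned, visit-by-visit Pearson correlations),
    fits a kinetic Ising model (a binary, one-step-memory generalized
    linear model) with external fields built from spatial, theta-phase,
    head-direction, running-direction and speed covariates, and compares
    models by Akaike-corrected and held-out likelihood. Includes a
    synthetic grid-cell population generator (hexagonal rate maps, foraging
    trajectories, theta rhythm, rate-driven or Ising-driven spiking) with
    ground truth for end-to-end validation, grid-geometry estimation
    (spacing, orientation, spatial phase offsets, module assignment), and
    theta-phase analyses (phase extraction, preference, circular k-means,
    phase-precession classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
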