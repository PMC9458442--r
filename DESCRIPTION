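Package: flipmsm
Title: Markov State Model Kinetics of DNA Base Flipping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic analysis of damaged-base flipping in DNA duplexes from
    molecular dynamics trajectories. Computes base-flipping collective
    variables (center-of-mass separation, pseudodihedral flip angle,
    hydrogen-bond occupancy, RMSD/RMSF), builds pairwise-distance feature
    matrices, reduces them by time-lagged independent component analysis
    (TICA), clusters microstates, estimates reversible maximum-likelihood
    Markov state models with Chapman-Kolmogorov validation, coarse-grains
    to metastable macrostates by PCCA+, converts stationary weights to free
    energies, and decomposes transition-path-theory flux into pathways.
    Also provides a one-dimensional extended-system adaptive-biasing-force
    plus metadynamics (meta-eABF) sampler with a CZAR free-energy estimator
    for potential-of-mean-force and barrier extraction on analytic
    landscapes, and synthetic-data generators (discrete Markov chains,
    overdamped Langevin dynamics on multi-well potentials, toy DNA duplex
    geometries) with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    igraph,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
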