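Package: cetasym
Title: Cranial Asymmetry Quantification and Phylogenetic Comparative
    Modelling for Cetacean Skulls
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies bilateral asymmetry of 3D cranial landmark
    configurations by comparing each specimen against its computer-mirrored
    symmetric reference (per-landmark displacement radii in spherical
    coordinates, specimen and group summaries), with thin-plate-spline
    estimation of missing landmarks and generalized Procrustes
    superimposition.  Models the evolution of the resulting asymmetry score
    on time-calibrated phylogenies: reversible-jump MCMC over relaxed
    Brownian motion with branch rate shifts and trait jumps, maximum
    likelihood fitting and AIC ranking of multi-regime Brownian motion and
    Ornstein-Uhlenbeck models on painted trees, Mk discrete-character fits,
    and phylogenetic ANOVA via generalized least squares with a Pagel's
    lambda correlation structure and Benjamini-Hochberg control.  Includes a
    synthetic-data module generating stylised skull landmark sets, trees,
    and traits with planted regimes, shifts, and jumps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
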