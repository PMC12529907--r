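Package: cgmembrane
Title: Coarse-Grained Phosphocholine Lipid Membranes: Force-Field
    Parametrization and Elasticity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and analysing coarse-grained (CG) models
    of phosphatidylcholine lipid bilayers. Provides center-of-mass mapping
    of atomistic structures onto 2:1/3:1/4:1 CG beads (including 2:1 water
    pairing), a harmonic-bond/harmonic-angle/Lennard-Jones force field with
    Lorentz-Berthelot mixing and configurable 1-2/1-3 exclusions, membrane
    structural estimators (area per lipid, phosphate-to-phosphate and
    hydrophobic thickness, vesicle radial profiles), bending-modulus
    estimation by the real-space fluctuation splay method, area
    compressibility from projected-area and local-thickness fluctuations,
    a compiled toy Langevin molecular-dynamics engine, particle swarm
    optimization of interaction parameters against weighted experimental
    targets, and Sobol-perturbation sensitivity analysis with partial
    correlation coefficients. Synthetic generators for bilayers, vesicles,
    splay-angle samples and area series make every estimator testable
    without external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
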