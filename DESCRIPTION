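Package: cortosim
Title: Agent-Based Simulation of Actomyosin Cortices in Deformable Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Brownian-dynamics simulation of a contractile
    actomyosin network (semiflexible actin filaments, two-armed cross-linkers,
    bipolar myosin mini-filaments) coupled to a cell-sized deformable
    triangulated membrane. Reproduces spontaneous bleb formation by two
    mechanisms, detachment of an intact cortex from the membrane and rupture
    of the cortex through tension-driven filament severing, together with a
    companion analytical theory of bleb initiation based on Bell-kinetics
    linker unbinding under Laplace pressure. Includes network self-assembly
    in cortical-shell or volume-spanning geometries, force-dependent binding
    kinetics, threshold severing, tension and bleb measurement, morphology
    classification, local coupling/connectivity perturbations, and
    phase-diagram prediction of the initiation mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
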