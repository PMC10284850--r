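Package: t1phase
Title: Multi-Phase Field Simulation and T1 Transition Analysis for
    Confluent Cell Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-dimensional confluent monolayer of active
    deformable cells with a conserved multi-phase field model
    (Cahn-Hilliard free energy plus pairwise repulsion/adhesion,
    self-propulsion aligned to cell elongation), using a semi-implicit
    Fourier-spectral solver on a periodic grid. Detects T1
    neighbour-exchange events from contact-graph time series, localises
    their epicenters by the geometric median of the participating cells,
    and computes event-aligned statistics: coarse-grained energy
    profiles, durations with Gamma fits, shape index and
    centre-of-mass-velocity profiles, gap fraction, tissue flow fields
    and chains of nearby events.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: fftw3
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
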