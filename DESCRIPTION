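Package: biolgca
Title: Biological Lattice-Gas Cellular Automata for Single and Collective
    Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of biological lattice-gas cellular
    automata (BIO-LGCA): synchronous, velocity-channel on-lattice models of
    single and collective cell migration. Provides the update cycle
    (stochastic reorientation, birth/death, phenotypic switching,
    deterministic propagation), a library of reorientation rules (random
    walk, chemotaxis, haptotaxis, contact guidance, polar alignment,
    adhesion, and a combined invasion rule with aggregation, alignment and
    resting interactions), derivation of rules from self-propelled-particle
    potentials via the stationary Fokker-Planck distribution and from
    observable time series via maximum caliber, and mean-field machinery:
    the adhesion finite-difference equation with its dispersion relation
    and critical wavelength, and the invasion model's lattice-Boltzmann
    steady state, Boltzmann propagator and four-phase classification
    (diffusive, collective, aggregation, jammed).
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
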