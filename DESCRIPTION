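Package: statenav
Title: State-Dependent Sodium Channel Block: Coupled-Equilibrium
    Inference, Gating Kinetics and Binding-Site Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for studying state-dependent block of
    voltage-gated sodium channels by small molecules such as cannabidiol.
    Implements the modulated-receptor coupled-equilibrium model relating
    availability-curve shifts to resting- and inactivated-state
    dissociation constants, a six-state Markov model of gating with
    state-dependent drug binding driven by piecewise-constant voltage
    protocols, Boltzmann and Hill curve fitting with drift correction,
    seeded synthetic-data generators for every input the analysis chain
    consumes, and geometric annotation of ligand binding sites
    (contacts, hydrogen bonds, aromatic stacking, rigid-body
    superposition) from atomic coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
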