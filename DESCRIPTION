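Package: retinox
Title: Hemodynamics and Oxygen Transport in Heterogeneous Retinal Arteriolar Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for blood flow and oxygen transport in
    heterogeneous retinal arteriolar networks coupled to lumped capillary and
    venular compartments. Provides a seeded generator of arteriolar trees with
    order-dependent diameters, a Poiseuille flow solver with successive
    over-relaxation and empirical hematocrit-dependent apparent viscosity,
    a vascular smooth muscle flow-regulation model (myogenic, shear and
    conducted metabolic responses), a Green's-function solver for tissue
    oxygen fields around discrete vessel sources with a finite-difference
    validator, Krogh-cylinder oxygen transport in capillary compartments,
    and reporting of oxygen extraction fraction and tissue hypoxia metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    deSolve
Config/testthat/edition: 3
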