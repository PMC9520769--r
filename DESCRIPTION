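Package: npmicroenv
Title: Nutrient Microenvironments of 2D and 3D Nucleus Pulposus Cell Cultures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finite-volume reaction-diffusion simulation of the local oxygen,
    glucose, lactate and pH microenvironments experienced by nucleus pulposus
    cells in common in vitro culture systems: 2D monolayer expansion in plates
    and flasks, and 3D alginate beads, cylindrical hydrogel constructs and
    pellet/microaggregate cultures.  Incubator gas settings (normoxia,
    physioxia, hypoxia) are converted to dissolved-oxygen boundary conditions
    by Henry's law; cellular metabolism follows pH- and oxygen-dependent
    Michaelis-Menten oxygen consumption, glucose-limited glucose consumption
    and ratio-coupled, pH-modulated lactate production; monolayer populations
    grow exponentially to a confluency cap; media exchanges are instantaneous
    reset events.  Ships a registry of standard culture scenarios, a
    randomized scenario generator for property testing, stiffness-robust
    transient and steady-state solvers on planar, spherical and axisymmetric
    meshes, a reduced-order multi-bead compartment model, and reporting and
    command-line front ends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
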