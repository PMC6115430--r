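Package: neovent
Title: Reduced-Order Simulation of High-Frequency Oscillatory Ventilation
    in the Preterm Lung
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale model of gas flow and oxygen transport during
    high-frequency oscillatory ventilation (HFOV) of a preterm infant.
    Generates a morphometric dichotomous airway tree calibrated to a
    prescribed anatomical dead space, closes each generation-seven outlet
    with a lumped resistance-compliance terminal unit parameterised from
    infant lung function testing (single-occlusion technique), applies
    HFOV ventilator boundary conditions with an uncuffed endotracheal
    tube leak, solves the unsteady 0D airway network with implicit time
    stepping, advects and diffuses oxygen along the tree with a 1D
    finite-volume scheme, and post-processes the result into flow-regime,
    pendelluft, oxygen-delivery and leak diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
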