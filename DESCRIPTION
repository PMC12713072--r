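Package: lyosim
Title: Mechanistic Simulation of Continuous Lyophilization in Suspended Vials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mechanistic process simulator for continuous lyophilization
    (freeze drying) of suspended vials. Covers the full cycle: freezing with
    vacuum-induced surface freezing (VISF) and deterministic or stochastic
    (Poisson-process) ice nucleation, primary drying as a Stefan-type
    moving-boundary sublimation problem solved on a Landau-transformed grid,
    secondary drying with linear-driving-force desorption of bound water, and
    a dynamic chamber vapor balance for condenser-failure analysis. Includes
    radiative-convective heat-transfer primitives for suspended vials,
    protocol scheduling, Monte-Carlo nucleation ensembles, and bundled
    scenario fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
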