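Package: pcslosh
Title: Two-Phase Sloshing, Wall Shear Stress and Oxygen Transfer in
    Agitated Platelet-Concentrate Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational model of platelet-concentrate (PC)
    storage under flatbed agitation.  A two-dimensional volume-of-fluid
    (VOF) free-surface solver with continuum-surface-force surface
    tension and PISO pressure-velocity coupling simulates sinusoidal
    agitation of a partially filled rigid container.  Post-processing
    computes liquid-volume-averaged velocity, wall shear stress,
    gas-liquid interfacial area, Higbie penetration-theory liquid-side
    mass-transfer coefficients, and container-permeability-limited total
    oxygen transfer via a resistance-in-series model.  Includes the
    regression analyses used to relate these metrics to agitation
    frequency, a synthetic bead-tracking generator emulating
    particle-tracking validation experiments, and a mesh-independence
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
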