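Package: tumourperf
Title: Multiscale Four-Compartment Model of Fluid and Drug Transport in Vascular Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates blood and chemotherapy transport in a vascularised
    tumour using a homogenised four-compartment continuum model (arterioles,
    venules, capillaries, interstitium). Provides periodic unit-cell
    permeability upscaling for explicit vessel-network topologies, a coupled
    Darcy pressure solver on a 2D dorsal skinfold chamber geometry,
    inter-region perfusion fluxes and their optimisation over the capillary
    composite parameter, a four-exponential plasma pharmacokinetic model for
    vinblastine, chamber-scale drug transport under injection and constant
    perfusion dosing, and interstitial volume-fraction (cell-kill) dynamics
    with second-dose timing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
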