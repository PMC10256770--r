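Package: nanowarm
Title: Simulation and Analysis Tools for Organ Vitrification and Nanowarming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the physical and functional analysis pipeline used in
    kidney vitrification and nanowarming studies: construction and evaluation
    of cryoprotective-agent (CPA) perfusion loading/unloading protocols;
    Krogh-cylinder mass-transport simulation of CPA and water exchange with
    Kedem-Katchalsky membrane fluxes; thermal-history analysis against
    critical cooling/warming rates; differential scanning calorimetry (DSC)
    ice-fraction and critical-rate estimation; micro-CT Hounsfield-unit
    calibration and vitrified/frozen classification; normothermic machine
    perfusion (NMP) functional metrics with group-comparison statistics; and
    post-transplant laboratory-trajectory summaries. A deterministic
    synthetic-data generator reproduces the statistical structure of each
    input so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
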