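Package: sensokin
Title: Adsorption-Limited Electrochemical Detection Modelling for Serotonin Biosensors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models adsorption-limited electrochemical detection of serotonin
    (5-HT) at surface-binding electrodes by coupling Langmuir adsorption
    kinetics to the adsorption-limited peak-current equation. Provides forward
    prediction of adsorbed moles and anodic peak current, nonlinear
    least-squares estimation of binding parameters (K_D, k_on, k_off, total
    site count) from calibration data, simulation and fitting of per-cycle
    electrode fouling, sensor characterization (sensitivity, linear range,
    LOD/LOQ), baseline-corrected peak extraction from cyclic voltammograms,
    seeded synthetic-data generators for all inputs, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
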