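Package: hemopulse
Title: Multimodal Cardiovascular and Hemodynamic Signal Processing for MEG Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for continuous, cuffless blood-pressure oscillation
    estimation from pulse transit time between fibre-optic accelerometer
    channels (chest and neck) or between MEG cardiac artifacts and a neck
    accelerometer, together with beat-to-beat heart rate, accelerometer-derived
    respiration, modified Beer-Lambert conversion of dual-wavelength NIRS
    intensities to hemoglobin concentration changes, breath-hold event-locked
    epoch averaging, and a Welch power-spectrum device-compatibility report.
    Includes a synthetic multimodal signal simulator with known ground truth
    (latent blood pressure, heart rate, respiration, beat times and per-beat
    transit times) so every stage of the pipeline can be validated against a
    recovery oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
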