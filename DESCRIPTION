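Package: vasodyn
Title: Timing Analysis of Neurovascular and Hypercapnic Vascular Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of cerebrovascular imaging and
    physiology signals around brief hypercapnic (CO2) challenges and whisker
    stimulation: seeded synthetic generators for line-scan kymographs,
    two-channel ratiometric pH recordings, respiration/blood-pressure traces and
    functional-ultrasound slow-time ensembles; kymograph velocimetry (line-scan
    PIV and streak-angle) and vessel diameter extraction; z-score normalisation,
    trial averaging and blood-flow computation; response-onset timing by
    nonlinear model fitting with a 10%-of-peak rule; ratiometric pH-sensor
    sigmoid calibration and inversion; SVD clutter filtering, power Doppler and
    axial-velocity band separation; and a response-additivity (occlusion) test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    signal,
    jsonlite,
    tiff,
    yaml,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
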