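Package: cgflow
Title: Ratiometric FRET Analysis of cGMP Dynamics in Platelet Thrombi Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of shear-dependent cGMP signaling in platelet
    thrombi from multi-channel time-lapse fluorescence movies. Provides
    dynamic thrombus segmentation with a core/periphery partition,
    background-corrected ratiometric FRET (CFP/YFP) and Fura-2 (340/380)
    trace extraction, Hill-type cGMP sensor calibration with saturation
    handling, thrombus growth and dissolution kinetics, cGMP-to-calcium
    lead-lag estimation, flow-chamber shear hydrodynamics, the statistical
    tests used for such experiments, and a synthetic movie generator with
    full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
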