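Package: nanosensR
Title: Ratiometric Fluorescent Nanosensor pH Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for intracellular pH measurement with ratiometric
    fluorescent nanosensors. Fits and inverts the sigmoidal ratio-versus-pH
    calibration curve, runs the pixel-level two-channel image-analysis
    pipeline (background subtraction, reference-channel masking, automatic
    threshold selection, intensity weighting, pH conversion, weighted
    histograms, region analysis and colour maps), designs citrate-phosphate
    universal calibration buffers with a polyprotic charge-balance solver,
    and simulates two-channel micrographs with known ground truth so the
    whole pipeline can be validated without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
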