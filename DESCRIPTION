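Package: endopol
Title: Polarimetric Endoscopy Simulation, Reconstruction and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for snapshot polarimetric endoscopy and benchtop Mueller
    polarimetry of tissue. Simulates division-of-focal-plane (DoFP)
    micro-polarizer camera mosaics from ground-truth polarimetric scenes,
    reconstructs partial-Stokes retardance and circular-depolarization maps
    (with fixed-pattern correction, bilinear demosaicing, exposure masking
    and gamma correction), models a polarization state generator/analyser
    Mueller polarimeter with least-squares Mueller-matrix estimation and the
    Lu-Chipman polar decomposition, and provides the downstream quantitative
    layer: RMS contrast, grid-unit ROI statistics with Mann-Whitney
    comparison, linear-SVM tissue classification with ROC/AUC, and an
    HSV-based retardance index for polarization microscopy images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    tools,
    utils,
    jsonlite,
    tiff,
    png,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
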