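Package: deformacyte
Title: Combined Electro-Optical Deformability Cytometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for a combined electro-optical
    deformability cytometer. Generates synthetic differential impedance traces
    (anti-symmetric double-Gaussian events) and impedance-triggered brightfield
    frames of cells deformed in viscoelastic shear flow; detects impedance
    events to recover transit time, velocity, electrical diameter and
    electrical deformability; segments cell images and fits moment-based
    ellipses for optical deformability; correlates the two modalities,
    quantifies frame coincidence, applies a lateral-position gate that removes
    the near-wall tear-drop artefact; and fits three-parameter Hill
    dose-response curves to recover EC50 values.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    tiff,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
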