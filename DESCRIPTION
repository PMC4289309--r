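Package: sprcal
Title: Objective-Based Surface Plasmon Resonance Imaging Optics and
    Depth Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative tools for high-resolution surface plasmon
    resonance (SPR) imaging through a high numerical aperture objective:
    multilayer Fresnel (transfer-matrix) reflectance with complex optical
    constants, back-focal-plane illumination geometry and crescent masks,
    evanescent-field penetration depth and plasmon propagation length,
    synthetic SPR and bright-field image simulation of reference
    microspheres and point sources, and the bead-based image-analysis
    pipeline that measures the detectable penetration depth of the
    evanescent field from bright-field / SPR image pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    graphics,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
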