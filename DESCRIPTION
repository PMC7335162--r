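Package: foramXRF
Title: Nano-XRF Analysis of Trace-Metal Layering in Foraminifer Test Walls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for intra-test trace-metal analysis of planktic foraminifer
    chamber walls from synchrotron X-ray fluorescence (XRF) count maps. Provides
    a parametric generator of layered wall models (inner calcitic layer, primary
    organic zone, outer calcitic layer, gametogenic crust) that renders
    Poisson-noisy element maps; rectangle-averaged profile extraction with
    Poisson-propagated uncertainties; elemental-ratio traces; nano-band
    detection via the finite-difference second derivative with propagated
    significance thresholds; Ca-profile wall-layer segmentation with per-layer
    enrichment and cross-element correlation statistics; and fundamental-
    parameter semi-quantification with Beer-Lambert self-absorption matrix
    corrections for thin lamellae and thick slabs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
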