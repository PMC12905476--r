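Package: stemmorph
Title: Outline Morphometrics and Stemma Visual-Field Reconstruction for
    Lacewing Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for comparing larval neuropteran
    (lacewing) head shapes and reconstructing the visual fields of their
    simple eyes (stemmata). Provides elliptical Fourier analysis of
    closed head-plus-stylet outlines with harmonic-power calibration,
    covariance-based principal component morphospaces with convex-hull
    occupancy and outlier detection, log-log allometry of lens diameter
    against head length with above-trend flagging, and a
    two-dimensional geometric-optics model of flat-lensed stemmata
    including flat-interface Snell refraction, binocular overlap of the
    left and right fields, and the relation of the stereoscopic region
    to the prey-capture range of the stylets. Synthetic-data generators
    emulate digitized head outlines, measurement tables, and head/eye
    layouts so the full pipeline is testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
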