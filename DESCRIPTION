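Package: spindletwist
Title: Elastic-Rod Modelling of Microtubule Bundle Shapes and Spindle Chirality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the chirality of the mitotic spindle from 3D
    traces of microtubule bundles and to estimate the twisting and bending
    moments that shape them. Implements the small-angle solutions of a
    Kirchhoff elastic rod spanning two spindle-pole spheres under balanced
    pole torques, a helicity statistic (azimuthal twist of a bundle per unit
    height along the spindle axis), trace calibration and selection filters
    for confocal z-stack data, a constrained shape-fitting procedure that
    recovers pole torques from traced bundles, and a synthetic-spindle
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
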