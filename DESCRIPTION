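Package: tomstem
Title: Stem Digitization and Procedural Growth Models for Potted Tomato Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for digitizing and visualizing potted greenhouse tomato
    plants from registered RGB-D image pairs. Implements an automatic
    four-step stem detection and segmentation pipeline (depth-window
    masking, Zhang-Suen thinning, progressive probabilistic Hough line
    detection, and valley localization on the plant breadth histogram by
    iterated Otsu thresholding with geometric false-positive removal),
    organ texture extraction into a growth-phase-indexed database, and a
    segment-level evaluation protocol (false negative, true positive,
    error and accuracy rates). A parametric L-system engine grows virtual
    cherry and ordinary tomato plants from choice-string axioms, interprets
    them into 3D scene graphs with Bezier-surface leaves, branch bending
    and fruit ripening, and exports Wavefront OBJ bundles. A synthetic
    RGB-D renderer emulates a structured-light depth camera so the whole
    detection pipeline can be exercised and benchmarked without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
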