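Package: spheroidgeom
Title: 3D Nucleus Geometry, Division-Axis Orientation and Mitosis Timing in
    Tumour Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional geometry of cell nuclei and the
    orientation of cell divisions in multicellular tumour spheroids imaged by
    light-sheet fluorescence microscopy. Ellipsoids are fitted to manually
    delimited nucleus boundary points by algebraic least squares; the spheroid
    surface is extracted from a fluorescence z-stack as the triangulated convex
    hull of the thresholded volume; nucleus elongation (L1/L3 aspect ratio),
    depth below the surface and the angle of the long axis (or of the division
    axis, the shortest axis of the metaphase-plate ellipsoid) to the local
    surface normal are then measured. Also converts time-lapse mitosis event
    annotations into prometaphase and metaphase durations with censoring, and
    ships a ground-truthed synthetic spheroid phantom generator so every stage
    of the pipeline can be validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
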