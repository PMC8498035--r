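Package: canalplane
Title: Spatial Attitude of the Human Semicircular Canals from Inner-Ear Centerlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the plane orientation (spatial attitude) of the three
    semicircular canals from inner-ear centerline models. Identifies the canal
    rings and anatomical key points from the centerline graph topology, builds a
    standard head coordinate frame from the bilateral common-crus bifurcations
    and the lowest point of the eyeball, fits each canal plane by orthogonal
    least squares on a spline-resampled arc, and summarizes cohorts of canal
    normals with vector-mean and angle-mean directional statistics. Includes a
    synthetic labyrinth generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
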