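Package: craniex
Title: Geometric Simulation of Volume Expansion After Decompressive Craniectomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify how much extra intracranial volume a
    decompressive craniectomy can create. Reconstructs skull-defect
    contours on axial CT-like slices by mirror reflection of the intact
    contralateral outline, elevates the reconstructed contour outward to
    emulate post-operative brain and scalp bulging, stitches the per-slice
    contours into a watertight triangle mesh, and measures defect area,
    enclosed volume and volume-increasing rate. Also implements an
    idealized elliptical skull cross-section model in which the newly
    gained area for a given defect width and elevation height is obtained
    by rectangle-rule numerical integration, including the plateau
    behaviour of the gain as the defect widens and a closed-form estimate
    of the maximal scalp elevation height. A phantom generator produces
    synthetic CT-like bone-mask slice stacks for end-to-end testing
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    tibble,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
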