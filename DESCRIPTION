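Package: tubetrace
Title: Stepwise Vector Tracking and Reconstruction of Tubular Structures
    in Volumetric Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated 3D tracking, segmentation and reconstruction of
    epithelial tubules (renal nephrons, seminiferous tubules) in cleared-tissue
    light-sheet volumes. Follows each tubule by stepwise vector tracking with
    orthogonal cross-section segmentation, adaptive parameter scaling, rotational
    search and a two-stage multi-hypothesis troubleshooting module; turns the
    tracked cross-sections into voxel-level reconstructions, straightened views,
    morphometric profiles (length, diameter, curvature, torsion), whole-tubule
    nuclei cytometry, and spermatogenic-wave staging of seminiferous tubule
    cross-sections. Includes a parametric phantom generator with complete ground
    truth for validation, and a file-based human-in-the-loop correction queue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    tiff,
    yaml,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
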