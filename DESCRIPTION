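Package: spinemorph
Title: Dendritic Spine Morphometry, Segmentation Validation and Tracking in 3D
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis core for dendritic spine quantification from 3D fluorescence
    microscopy. Takes a volume plus a multi-class semantic label map
    (background/dendrite/soma/spine head/spine neck) produced by any external
    segmenter, extracts individual spine instances, filters spurious detections,
    and computes per-spine and per-dendrite morphometry on the physical
    (anisotropic, micrometre) grid: volumes, centroids, intensity statistics,
    spine length, neck length, head width, distance to the dendrite shaft, and
    Euclidean and geodesic distances from the soma. Includes pixel- and
    object-level segmentation validation (Dice, IoU, greedy IoU matching with
    precision/recall/F1 curves, surface Hausdorff distance), longitudinal spine
    tracking with rigid phase-correlation registration and formation/elimination
    classification, SWC skeleton export, and a synthetic phantom generator with
    exact ground truth plus imaging-degradation and augmentation operators so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
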