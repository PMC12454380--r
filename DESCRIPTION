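Package: corncloud
Title: Point-Cloud Segmentation and Trait Extraction for Maize Seedling Trays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for 3D phenotyping of maize seedlings grown in cultivation
    trays, working from photogrammetric point clouds. Provides labeled
    point-cloud text I/O, a synthetic tray-scene generator with known
    ground-truth traits, the six standard point-cloud augmentations, a
    CBAM-augmented hierarchical point network (set abstraction with
    multi-scale grouping, feature propagation) for seedling/background
    semantic segmentation, adaptive-eps density clustering (CornDBSCAN) for
    instance separation with Hungarian matching, segmentation metrics, and
    per-plant trait extraction: plant height, canopy width, voxel volume and
    ball-pivoting mesh surface area, after RANSAC ground-plane alignment and
    reference-object scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
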