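Package: grain3d
Title: Grain Morphometry and Classification from Structured-Light Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for 3D cereal grain phenotyping from
    structured-light scans. Segments individual grains out of a scanned
    scene point cloud (RANSAC stage-plane fit followed by normal/curvature
    region growing), reconstructs each grain surface by greedy projection
    triangulation, and computes 25 phenotypic traits: oriented-bounding-box
    length, width and thickness, Heron-sum mesh surface area,
    prism-projection volume, principal-plane projected areas, perimeters
    and compactness indices, and the derived shape ratios. Includes a
    synthetic scene generator (superellipsoid grains standing on a stage
    plane, scanner-like sampling density and surface noise) so every stage
    is testable against analytic solids, plus the trait standardization,
    Pearson correlation, error-metric (MAPE, RMSE, R squared) and
    tenfold cross-validated classification protocol with six machine
    learning back ends and feature-importance ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    FNN,
    interp,
    data.table,
    jsonlite,
    stats,
    utils,
    rpart,
    ranger,
    e1071,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
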