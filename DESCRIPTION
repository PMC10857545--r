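Package: cowmorph
Title: Automated Body Measurement of Dairy Cows from 3D Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Toolkit for non-contact conformation measurement of standing
    dairy cattle from 3D point clouds. Provides PLY input/output and rigid
    transform algebra, RANSAC extraction of the ground and fence planes,
    voxel-grid downsampling, statistical outlier removal and coordinate
    normalization, point-to-point ICP with fitness/inlier-RMSE registration
    scoring, anatomical keypoint detection by distance-field regression with
    a PointNet-style per-point network trained in R, geometric measurement
    of stature height, rump angle, rump width and front-teat length, and
    mapping of each trait to a 9-level linear conformation score. A
    parametric generator of cow-shaped scenes with exact ground-truth
    keypoints and measurements makes every stage testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
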