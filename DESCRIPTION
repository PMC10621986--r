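Package: larvapose
Title: Physical-Model-Based 3-D Pose Estimation for Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markerless 3-D pose estimation of larval zebrafish from
    synchronized orthogonal camera views. Provides refraction-corrected camera
    calibration for a water-filled glass tank (separable bivariate cubic
    projection functions fitted to dot-grid correspondences, per-pixel ray
    lookup tables, nonlinear triangulation), a 22-parameter voxel-based
    physical model of the larva with accurate and lookup-table renderers,
    kernel-density resampling of pose ensembles and generation of annotated
    synthetic training images, two-round template-based pose optimization, a
    bottleneck-residual convolutional network for 2-D keypoint regression
    trained purely on rendered images, reconstruction of 3-D poses with eye
    disambiguation and arc-length spline resampling, masked-correlation
    prediction scoring, and bout-level 3-D swim kinematics with bootstrap and
    binomial statistics and SVD bending modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
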