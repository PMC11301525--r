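Package: adnexseg
Title: Two-Stage Segmentation of Adnexal Masses on Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated segmentation of ovarian/adnexal masses on
    2-D grayscale ultrasound images. A supervised U-net (implemented with
    compiled Armadillo kernels) labels pixels inside a bounding-box region
    of interest as mass or background; a defined refinement chain (resize to
    original ROI scale, hole filling, Gaussian smoothing with thresholding,
    largest-component selection) produces the final mask and boundary.
    Segmentation quality is scored with the Dice similarity coefficient and
    RHD-D, the ratio of the average Hausdorff distance between boundaries to
    the effective diameter of the reference outline. A second, unsupervised
    stage separates in-mass pixels into relative hypoechoic and hyperechoic
    components by two-cluster fuzzy c-means on a three-channel texture stack
    (grayscale, local entropy, local standard deviation). A seeded speckle
    phantom generator provides synthetic cohorts with per-pixel ground truth
    so the whole pipeline can be trained and evaluated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
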