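Package: cephmark
Title: Single-Stage 3D Cephalometric Landmarking by Heatmap Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Localizes cephalometric landmarks in CBCT-like 3D volumes with a
    single-stack 3D hourglass network trained by Gaussian-heatmap regression,
    and derives cephalometric characteristic measures (McNamara distances,
    Frankfort-frame vector components, SNA/SNB and plane angles) from the
    landmark coordinates. Includes volume and landmark I/O with isotropic
    resampling, a seeded synthetic skull-phantom generator for end-to-end
    testing without clinical data, and an evaluation suite (Euclidean
    distance, successful detection rate, Mann-Whitney U tests with
    Benjamini-Hochberg correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
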