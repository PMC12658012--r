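Package: fibseg
Title: Two-Stage 3D U-Net Segmentation of the Fibula from Lower-Extremity CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic segmentation of the fibula bone from
    lower-extremity CT volumes for preoperative planning of mandibular
    reconstruction with free fibula flaps. Implements a coarse-to-fine
    two-step 3D U-Net pipeline in two variants: a bilateral approach that
    localizes both fibulae jointly on the down-sampled field of view, and
    a unilateral approach that splits the CT at the field-of-view
    mid-plane and mirrors the right half so that a single network serves
    both sides. Includes Expansion Transfer Learning between the two
    stages, morphological and marching-cubes style mesh post-processing,
    surface-distance evaluation metrics (Dice, average surface distance,
    95th-percentile Hausdorff distance) with a surgery-specific
    region-of-interest restriction, and a seeded synthetic lower-limb CT
    phantom generator for end-to-end testing when clinical data are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
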