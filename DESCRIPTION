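Package: caliper
Title: Automated Callosal Angle Measurement from 3D T1-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the callosal angle (CA), a radiological marker of
    normal pressure hydrocephalus, from 3D T1-weighted MRI volumes given
    anterior/posterior commissure (AC/PC) landmarks. The pipeline
    reorients volumes to RAS, resamples them to an isotropic cube,
    extracts the oblique coronal plane perpendicular to the AC-PC line at
    the PC, delineates the medial walls of the lateral ventricles by
    maximum-margin separation, perpendicular ray casting and
    inlier-maximizing line search, and reports the angle between the two
    wall lines. Ships synthetic wedge phantoms with analytic ground
    truth, a perturbation-sensitivity experiment for PC shifts and plane
    rotations, landmark and segmentation evaluation metrics (Euclidean
    error, PCK@10, Dice, Hausdorff), and method-agreement statistics
    (MAE, Bland-Altman limits of agreement, Pearson correlation, 90
    degree classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    withr,
    stats,
    grDevices,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
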