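Package: sinusvol
Title: Automated CT Volumetry of the Maxillary Sinuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fully automated segmentation and volumetry of the left and
    right maxillary sinuses on head CT. A per-slice hybrid pipeline
    (Hounsfield-unit bone thresholding, morphological opening,
    watershed partitioning, and a rule-based basin selector using
    position, shape and symmetry) is seeded on the middle slice and
    propagated outward to assemble a 3D region per sinus. Region voxels
    are banded into air and involvement (mucosal thickening, cysts,
    fluid) classes, converted to volumes in cubic centimetres, and
    exported as NIfTI label maps, JSON/CSV reports and triangulated
    surface meshes. Includes a parametric synthetic head-CT phantom
    with analytically known cavity volumes, and method-agreement
    statistics (percent difference, linear regression, Bland-Altman)
    for validating automated volumes against a reference standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    mgcv,
    patchwork,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
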