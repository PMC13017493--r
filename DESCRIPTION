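Package: canopytrial
Title: Spatial Adjustment and Canopy Phenomics for Modified Augmented Design Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing unreplicated field trials laid out as a
    Type-II Modified Augmented Design (MAD), with an emphasis on canopy
    phenomics in row crops such as soybean. Implements check-plot based
    spatial adjustment (adjustment by design structure and adjustment by
    regression), the intra-whole-plot error and relative-efficiency
    selection rule; LOWESS/logistic/quadratic fitting of trait time
    courses with information-criterion model selection and extraction of
    temporal parameters (peak value and day, canopy-closure dates,
    decline onset); Excess Green vegetation segmentation and percent
    canopy coverage, NDVI zonal statistics, and voxel-grid digital
    biomass from point clouds; Farquhar-von Caemmerer-Berry (FvCB) A-Ci
    curve fitting for Vcmax, Jmax and Rd with normalisation to 25 degrees
    C; and quadratic leaf-area-index versus yield optimum estimation. A
    synthetic-trial generator reproduces the statistical structure each
    stage assumes (MAD layouts, additive row/column gradients, sigmoidal
    time courses, two-class plot images, box-like canopy point clouds,
    FvCB-generated gas-exchange curves) so the whole pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
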