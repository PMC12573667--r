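Package: gridsurv
Title: Quadrat-Based Poisson Regression of Clonogenic Survival After
    GRID Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and modelling local clonogenic cell
    survival after spatially fractionated (GRID) X-irradiation in vitro.
    Provides a synthetic-data generator for striped, dotted and open dose
    patterns with colony placement as an inhomogeneous Poisson point
    process; radiochromic film dosimetry calibration via net optical
    density; peak-region segmentation and Euclidean distance-to-peak
    maps; co-registration and 1 mm^2 quadrat aggregation of colony
    centroids with dose and distance maps; Poisson generalized linear
    model fitting of linear-quadratic (LQ) and modified linear-quadratic
    (MLQ) survival models; and repeated stratified k-fold
    cross-validation with AIC/BIC/RMSE/MAE model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
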