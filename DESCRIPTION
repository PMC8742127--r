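Package: spdri
Title: Simulation and Calibration of Shifted-Position Diffuse Reflectance
    Imaging of Skin Capillaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelized Monte-Carlo simulation of diffuse reflectance from a
    seven-layer skin model containing capillary loops, and the downstream
    shifted-position diffuse reflectance imaging (SP-DRI) analysis chain:
    ratio-image normalization, Savitzky-Golay filtered cross-section
    profiles, the K_norm modulation statistic, linear calibration of K_norm
    against capillary diameter (intercept beta0, slope beta1), random-forest
    ranking of optical-property predictors, analytic two-exponential
    calibration surfaces, and calibration-free absolute diameter prediction
    with coefficient-of-variation summaries. Includes a fast surrogate data
    generator so the calibration and evaluation machinery can be exercised
    without photon transport.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    minpack.lm,
    randomForest,
    xgboost,
    EBImage,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
ByteCompile: true
RoxygenNote: 7.3.3
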