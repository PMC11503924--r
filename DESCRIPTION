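Package: nh3wt
Title: Hybrid Wavelet-Transform Machine Learning for Ammonia Prediction in Poultry Houses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ammonia (NH3) concentration in poultry houses from litter
    and air microclimate variables with a hybrid pipeline: multilevel discrete
    wavelet decomposition of each ordered predictor series, correlation-based
    selection of detail sub-series, reconstruction of denoised features, and
    regression with extreme learning machines, k-nearest neighbours, random
    forests, or a linear baseline. Includes a synthetic-data generator that
    emulates the statistical structure of broiler-house field measurements,
    a Monte-Carlo cross-validation grid search, and evaluation utilities
    (mean absolute error and Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
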