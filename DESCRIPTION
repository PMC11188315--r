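Package: gwrbf
Title: Grey Wolf Optimised Radial Basis Function Networks for Soil
    Nutrient and Yield Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for plot-level soil nutrient and crop yield modelling
    in tree-fruit orchards. Implements a Gaussian radial basis function
    (RBF) regression network whose full parameter vector (centres,
    widths, output weights and bias) is trained by a grey wolf optimizer
    with mean relative prediction error as the fitness, optionally
    polished by gradient descent. Includes z-score standardization with
    train-only parameter estimation, MAPE/MAE/R-squared evaluation and
    model-comparison tables, forward stepwise multiple linear regression
    for yield, a plain RBF network and a backpropagation neural network
    as comparison baselines, a seeded synthetic soil-sample generator
    with planted ground truth, and a command-line interface for
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
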