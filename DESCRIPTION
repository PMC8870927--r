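Package: enoser
Title: Hybrid 1-D Convolutional and Random-Forest Regression for
    Electronic-Nose Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies food adulteration from metal-oxide-semiconductor
    (MOS) electronic-nose response curves.  Implements a compact
    one-dimensional convolutional backbone that learns features from
    10-sensor, 100-second conductivity-ratio (G/G0) curves, a
    random-forest regression head fitted on the frozen backbone features,
    and the classical stable-value baselines (support vector regression,
    random-forest regression, and a small feed-forward network), together
    with a seeded synthetic E-nose simulator, day-blocked dataset splits,
    grid-search cross-validation, and R-squared/RMSE/MAE reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    e1071,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
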