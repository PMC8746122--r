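Package: wbnet
Title: Backbone Extraction for Weighted Dynamic Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts the backbone of statistically irreducible ties from
    temporal networks with continuous weights, such as sliding-window dynamic
    functional connectivity (dFC) of resting-state fMRI. Each node carries two
    latent propensities whose pairwise products set the mean and standard
    deviation of a Gaussian null for that pair's temporal weights; the
    propensities are estimated by solving the model's nonlinear moment
    equations, and links whose weights exceed the fitted null's upper
    percentile in more than half of the time windows are admitted to the
    backbone. Includes autoregressive-randomization and phase-randomization
    surrogate baselines, a synthetic-data generator with known ground truth,
    and evaluation utilities (normality sweeps, window-size stability,
    injected-link detection AUC).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
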