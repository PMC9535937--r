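Package: lurtransfer
Title: Transfer-Learning Land-Use Regression for Mobile Air-Quality Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adapts land-use regression (LUR) models trained on short-term,
    on-road mobile air-quality measurements so that they predict long-term,
    near-road concentrations. Implements the mobile-only baselines
    (direction-constrained forward stepwise linear LUR and a tuned
    random-forest LUR), two instance-based transfer-learning models
    (Prior_RF, a random forest whose risk function is reweighted by a
    RuLSIF-estimated density ratio between long-term and mobile
    concentration distributions, and Two-stage TrAdaBoost.R2 boosting),
    the full long-term validation protocol (bootstrap repeats, 50/50 site
    splits, nMAE, nRMSE, squared-Pearson R-squared, improvement
    percentages), and a synthetic-scene generator that emulates a mobile
    campaign with on-road and daytime bias together with a sparse long-term
    near-road monitoring network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
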