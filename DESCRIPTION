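Package: userlift
Title: User-Lift Evaluation of Personalized Models for Longitudinal Subjective State
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates whether predictive models of longitudinal subjective
    state (e.g. daily stress or happiness self-reports) actually beat trivial
    per-person guessing. Implements the "user lift" statistic (personal
    baseline error minus model error) with an exact or Monte Carlo one-sample
    sign-flip permutation test of mean lift greater than zero; personal and
    population constant baselines (mode / mean); daily GPS location and
    mobility features built from two location clusterings (a Gaussian mixture
    over all samples with BIC-selected order, and K-means over stationary
    points) including location entropy, circadian movement, and the minimum
    enclosing circle radius; personal and population predictive models under
    leave-one-out cross-validation with inner 10-fold hyperparameter
    selection; and a synthetic cohort generator emulating smartphone-sensing
    studies (sparse GPS around recurrent dwelling locations, Likert
    self-reports with large between-user and small within-user variance)
    under null or planted-signal regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    withr,
    mclust,
    glmnet,
    e1071,
    randomForest,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
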