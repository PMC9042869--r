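Package: eegcpm
Title: Connectome-Based Predictive Modeling of Depression Severity from
    EEG Phase-Locking Networks
Version: 0.1.0
Authors@R:
    person("eegcpm", "developers", email = "eegcpm@example.org",
           role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) of depression
    severity from band-limited phase-locking connectomes. Builds phase
    locking value (PLV) connectivity matrices from regional time series
    in the canonical EEG bands, harmonizes BDI/HDRS psychometric scores
    across scales, selects score-correlated edges under FDR control into
    positive and negative tails, summarizes subjects by network strength,
    and fits epsilon support-vector regression to predict standardized
    scores. Includes leakage-free k-fold cross-validation with a
    permutation null on the mean absolute error, consensus-network
    extraction, external validation with frozen standardization
    parameters, confound screening via (point-biserial and partial)
    correlation, and a synthetic cohort generator with planted
    score-correlated edges for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    matrixStats,
    optparse,
    quadprog,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
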