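Package: fcRecovery
Title: Longitudinal Functional-Network Recovery Analysis from ROI Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the normalization of resting-state
    functional brain networks alongside behavioural (language) recovery in
    longitudinal patient cohorts. Provides ROI-level time-series cleaning
    (framewise-displacement scrubbing, 36-parameter nuisance regression,
    zero-phase band-pass filtering), Pearson / Fisher-z functional-connectivity
    network construction with correlation thresholding, weighted global and
    local network efficiency and connectivity strength, control-referenced
    Z-scores, aphasia-quotient scoring with recovery classification and
    recovery-ratio statistics, and a synthetic-cohort generator producing
    controls and longitudinal patients with block-structured covariance for
    end-to-end testing without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    signal,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'fc-network.R'
    'fcRecovery-package.R'
    'graph-metrics.R'
    'io.R'
    'pipeline.R'
    'preprocess.R'
    'recovery-stats.R'
    'synthetic-cohort.R'
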