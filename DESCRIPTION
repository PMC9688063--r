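Package: microstates
Title: EEG Microstate Analysis and Bayesian-Optimized Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resting-state EEG microstate analysis: global field power (GFP)
    computation and peak detection, polarity-invariant modified K-means
    clustering of GFP-peak topographies with the global explained variance
    (GEV) criterion, canonical A-D labeling, backfitting, and per-epoch
    microstate features (occurrence, duration, coverage, mean GFP, and the
    microstate-map-correlation statistic). Includes chi-square feature
    ranking, exact interventional Shapley explanations, and Bayesian
    optimization over a pool of classifiers with random-forest surrogates
    and expected-improvement acquisition, plus a seeded synthetic EEG cohort
    generator with known microstate ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    e1071,
    nnet,
    rpart,
    ranger,
    glmnet,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
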