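Package: ppactiv
Title: Psychophysiological Activation Analysis for Wearable Trader Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying psychophysiological (PP) activation from
    multichannel wearable recordings (blood volume pulse, electrodermal
    activity, skin temperature, heart rate, inter-beat intervals,
    accelerometry). Extracts eleven physiological features on a 1 Hz grid
    (time-domain heart-rate variability, electrodermal level/slope/response
    counts, blood-volume-pulse summaries, skin-temperature slope), scores
    activation as a causal expanding-window squared Mahalanobis distance,
    labels mild and extreme activation episodes, tests Granger causality
    between market-index fluctuations and activation with Holm-Bonferroni
    correction and Kolmogorov-Smirnov p-value diagnostics, fits an attribution
    regression of average daily activation on trader covariates, and computes
    transaction-centered event-study profiles. Includes a fully seeded
    synthetic cohort generator with planted ground truth so every stage of the
    pipeline can be validated against a recoverable truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    sandwich,
    lmtest
Config/testthat/edition: 3
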