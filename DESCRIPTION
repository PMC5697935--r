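Package: thetasync
Title: Punishment-Risk Encoding and VTA-mPFC Theta Synchrony Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured dual-region (medial
    prefrontal cortex and ventral tegmental area) electrophysiology recorded
    during an instrumental task with blockwise-varying punishment risk.
    Implements peri-event spike binning and baseline z-scoring, bias-corrected
    percent-explained-variance (omega PEV) encoding statistics with
    trial-shuffled pointwise and global significance bands, standardized
    regression coefficients for response direction, putative dopamine cell
    classification (rate/width criteria plus auROC reward-response PCA and
    Gaussian-mixture clustering), Gaussian-process factor analysis of
    simultaneously recorded populations with cross-validated dimensionality and
    trajectory-deviation response-time correlations, multitaper spectrograms
    and magnitude-squared coherence, bivariate spectral Granger causality with
    permutation confidence bounds, and spike-field phase locking
    (resampling-controlled mean resultant length, Rayleigh test, time-lagged
    directionality). A seeded synthetic-session generator reproduces the task's
    statistical structure so every stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
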