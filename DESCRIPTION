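Package: microstatr
Title: EEG Microstate Segmentation, Dynamics and Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Resting-state EEG microstate analysis: synthetic EEG generation
    with known microstate ground truth, deterministic preprocessing
    (zero-phase filtering, resampling, epoching, bad-channel repair,
    amplitude-based artifact rejection, average reference), polarity-invariant
    atomize-agglomerate hierarchical clustering (AAHC) of global-field-power
    peak topographies, template alignment and backfitting, microstate dynamics
    metrics (duration, occurrence, coverage, transition probabilities, global
    explained variance), group statistics with false-discovery-rate control,
    covariate-adjusted partial rank correlation, stepwise linear regression,
    and decision-tree classification with cross-validation and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    rpart,
    pROC,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
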