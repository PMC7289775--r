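Package: AHcascade
Title: Cascaded Detection of Apnea-Hypopnea Events from Nasal Flow and SpO2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects apnea-hypopnea (AH) events in single-night recordings of
    nasal airflow and pulse-oximetry oxygen saturation sampled at 8 Hz.
    Implements signal preprocessing (artifact masking, moving-average plus
    high-pass filtering, sliding-window segmentation, SpO2 time alignment),
    extraction of 19 morphological features per segment, a cascaded
    random-forest classifier (a 10-tree screen on 60-s windows gating a
    20-tree classifier on 10-s windows), rule-based run-length correction of
    the predicted label sequence into discrete events, apnea-hypopnea index
    (AHI) estimation with severity grading, and the associated evaluation
    metrics (confusion metrics, Bland-Altman agreement, Cohen's kappa). A
    synthetic polysomnography generator produces annotated recordings with
    the same morphology so the whole pipeline can be trained and tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    ranger,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
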