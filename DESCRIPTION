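Package: fluoroperf
Title: Fluorescence Perfusion Kinetics for Lesion Classification and
    Multi-Rater Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Fluoroperf", "Developers", email = "fluoroperf@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for indocyanine green (ICG)
    fluorescence-augmented characterisation of rectal lesions from
    dual-channel (white-light + near-infrared) endoscopy video, together
    with a multi-rater clinical-judgement analysis toolkit. Includes a
    synthetic dual-channel video and rater-response simulator with exact
    ground truth, normalized cross-correlation ROI tracking, time-intensity
    curve milestone extraction (time to peak, upslope, downslope, skew,
    centre of mass), tree-ensemble classification with patient-grouped
    cross-validation and patient-level aggregation, and rater statistics
    (Fleiss multi-rater kappa with large-sample confidence intervals,
    Likert confidence tables, diagnostic accuracy, Spearman correlation,
    and lesion size-estimation error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
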