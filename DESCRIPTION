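Package: sleepconcord
Title: Agreement Evaluation of Contactless Sleep Technologies Against
    Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for validating consumer and contactless sleep-tracking
    devices against polysomnography (PSG). Provides a hypnogram data model
    with stage-vocabulary harmonization (5-, 4-, 3- and 2-stage), epoch
    resolution conversion (60 s to 30 s), analysis-period handling and
    epoch pairing; all-night sleep summary measures (TST, SOL, WASO, SEFF,
    stage durations); paired-agreement statistics (Bland-Altman limits of
    agreement, minimum detectable change, symmetric mean absolute
    percentage error, standardized absolute difference, consistency
    intraclass correlation, Cohen's d); multi-resolution epoch-by-epoch
    concordance with cross-correlation lag alignment, confusion-matrix
    pooling and Matthews correlation coefficient; slow-wave-activity
    quantification from single-channel EEG; and a seeded synthetic cohort
    generator (Markov-chain sleep architecture plus parametric device
    error profiles) so the full pipeline can be exercised and calibrated
    without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
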