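Package: mmnpipe
Title: Simulation and Analysis of Multi-Feature Mismatch-Negativity Oddball EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for passive auditory oddball experiments probing formal
    (phonotactic probability) and temporal (syllable stress) predictability in
    speech. Generates pseudorandom multi-feature oddball stimulus sequences,
    synthesizes multichannel EEG with known mismatch-negativity (MMN) ground
    truth, preprocesses continuous data (band-pass and notch filtering,
    downsampling, ocular-artifact removal, epoching, baseline correction,
    amplitude-criterion rejection, mastoid re-referencing), applies the
    deviant/standard trial-selection and count-equalization rules, extracts
    identical-stimulus difference waves with MMN peak latency and mean
    amplitudes over frontocentral and centroparietal regions of interest, and
    runs within-subject factorial repeated-measures ANOVAs with Holm
    multiple-testing correction. Includes parameter-recovery and
    type-I-error simulation drivers for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
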