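Package: vigimark
Title: Vigilance-Task Outcome Prediction from Multichannel ECoG Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-trial prediction of vigilance-task performance (correct versus
    incorrect trials) from 10-channel electrocorticography. Implements independent
    component analysis for ocular-artifact removal, seventeen families of
    spectrotemporal and connectivity biomarkers (band powers, wavelet entropy,
    Hjorth parameters, phase-amplitude coupling, instantaneous amplitude and
    frequency, partial directed coherence, phase-locking, global coherence), and
    gradient-boosted classification with wrapper forward feature selection under
    nested cross-validation. A synthetic-session generator with per-trial ground
    truth carries the statistical structure the analysis assumes (fatigue drift,
    low-frequency power elevation on incorrect trials, wavelet-entropy drop,
    directed cross-channel coupling, frontal ocular artifacts), so the full
    pipeline is testable without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
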