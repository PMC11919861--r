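Package: vrdistress
Title: Distress Detection from Paired Wearable Heart-Rate Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based distress detection for virtual-reality sessions from
    paired chest-ECG and wrist blood-volume-pulse recordings. Provides a
    synthetic paired-recording generator driven by a shared ground-truth
    RR-interval process, device-format readers and writers (Empatica-style
    CSV, two-line-header ECG CSV, minimal EDF), QRS detection after Hamilton
    with template-matching R-peak correction, Elgendi-style pulse onset
    detection, ultra-short-term heart-rate features (10-s mean HR and RMSSD)
    with subject-specific baseline thresholds, per-window distress levels,
    event-coincidence analysis, and device-agreement statistics (SNR,
    correlations, MAE/RMSE, Bland-Altman, Wilcoxon signed-rank, Cliff's
    delta).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
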