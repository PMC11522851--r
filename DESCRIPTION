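Package: noctox
Title: Nocturnal Pulse Oximetry Analysis for Acute Mountain Sickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing overnight 1 Hz pulse-oximetry recordings
    collected during ascent to high altitude. Implements artefact rejection
    for wrist-oximeter SpO2 traces, desaturation-event detection with oxygen
    desaturation index and hypoxic-burden metrics, saturation frequency
    distributions with statistical moments, per-night feature extraction
    (overnight means, half-night change in SpO2, lowest moving averages),
    and a diagnostic statistics layer for acute mountain sickness
    classification: Mann-Whitney subgroup comparison with Hodges-Lehmann
    median differences, ROC analysis with Youden-index cutoffs, Bland-Altman
    agreement against arterialized capillary saturation, and exploratory
    Pearson correlations against Lake Louise symptom scores. A seeded
    synthetic expedition-cohort generator provides calibrated test data so
    the full pipeline runs without any device exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
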