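Package: holterst
Title: Ischemia Detection and Circadian Profiling from Multi-Day 12-Lead Holter ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multi-day ambulatory 12-lead ECG
    (Holter) recordings in patients with angina and non-obstructive coronary
    arteries. Detects and delineates heartbeats, reduces the waveform to
    per-10-second median heart rate and conduction intervals, computes
    per-lead median beats and measures ST-segment and T-wave deviations
    against each patient's own heart-rate-matched baseline median beat,
    detects ischemia events under a contiguous-lead and minimum-duration
    rule across a cutoff sweep, normalizes daily ischemia burden, scores
    symptom concurrency, profiles circadian conduction times in 3-hour bins,
    selects standardized resting 10-second segments, and summarizes
    diagnostic accuracy with Wilson score intervals, Fisher exact tests and
    bootstrap ROC curves. Includes a synthetic Holter cohort generator with
    ground truth for every injected feature.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
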