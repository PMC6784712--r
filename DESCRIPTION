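Package: lcosa
Title: Obstructive Sleep Apnea Screening from Under-Mattress Load-Cell Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end screening pipeline for obstructive sleep apnea (OSA)
    from contact-free, under-mattress load-cell recordings. Combines the four
    sensor channels into a single band-limited composite signal, extracts
    skewness and kurtosis of Fourier-coefficient magnitudes in narrow 0.02 Hz
    sub-bands, and grades severity with a two-stage classifier: a decision
    tree that separates normal from abnormal studies, followed by a linear
    regression that estimates the apnea-hypopnea index (AHI) for abnormal
    studies. Includes a windowed per-night AHI protocol with rolling-median
    outlier rejection, multi-night max-rule aggregation, a synthetic bed-signal
    simulator with known ground-truth event rates, leave-one-patient-out
    cross-validation, and a diagnostic-accuracy evaluation suite
    (confusion metrics, Bland-Altman agreement, paired comparisons) over
    packaged per-night study tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    rpart,
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
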