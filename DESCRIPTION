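Package: insolemetry
Title: Repeatability and Responsiveness Metrology for Instrumented-Insole Gait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for metrological analysis of plantar-pressure insole gait
    recordings. Simulates dual-foot 18-cell capacitive insole recordings at
    110 Hz under symmetric and split-belt asymmetric walking conditions with
    known ground truth, detects initial-contact and toe-off events from the
    summed pressure signal with Savitzky-Golay smoothing and thresholded
    derivative rules, extracts per-cycle stance, swing, single- and
    double-support durations and mean vertical force during single stance,
    and computes repeatability (standard error of measurement, ICC(3,k)) and
    responsiveness (minimum detectable difference at 95 percent confidence,
    effect size) with condition-level aggregation and classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
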