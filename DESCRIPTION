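Package: tmrsleep
Title: Targeted Memory Reactivation Sleep-EEG Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted-memory-reactivation (TMR) sleep
    EEG experiments: slow-wave and fast sleep-spindle detection with
    per-subject amplitude thresholds, slow-wave/spindle up-state coupling,
    cue-locked event-density and Morlet time-frequency statistics,
    cluster-based permutation tests over channel-frequency-time data, and
    signal-detection-theory scoring of two-alternative discrimination
    behavior. Includes a synthetic-data generator that injects slow waves,
    coupled spindle bursts and Bernoulli behavior with known ground truth,
    so every stage of the pipeline is testable end-to-end without access to
    raw polysomnography.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
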