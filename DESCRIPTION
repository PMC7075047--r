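Package: startler
Title: Acoustic Startle Reflex Quantification and Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies acoustic startle reflexes of tagged animals from
    triaxial accelerometer records (peak-to-peak VeDBA, maximum norm jerk,
    response latency), calibrates received sound levels from hydrophone
    recordings (SPL, SEL, spherical-spreading ear compensation, third-octave
    and rise-time-controlled noise pulse synthesis, echolocation click
    attribution), fits gamma and logistic dose-response GLMs with
    small-sample AICc model selection, and derives startle thresholds,
    rise-time thresholds and sensation levels against audiograms. Includes a
    synthetic-data generator that emulates the full experimental protocol so
    every stage of the pipeline can be exercised and validated without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
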