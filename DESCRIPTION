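Package: ntsprio
Title: Risk-Based Suspect and Non-Targeted Screening of LC-HRMS Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for risk-based prioritization of liquid
    chromatography electrospray high-resolution mass spectrometry (LC-ESI-HRMS)
    feature data. Provides molecular-formula and adduct mass arithmetic, a
    quality-control filter cascade (intensity, replicate reproducibility,
    blank ratio, peak quality, componentization, MS2 assembly), suspect-list
    screening with retention-time-index regression filtering, consensus
    structural annotation with confidence levels, response-factor based
    semi-quantification via ionization-efficiency transfer, toxicity-weighted
    priority scoring, and annotation-performance validation. A seeded
    synthetic-data generator produces complete truth-labeled experiments so
    every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
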