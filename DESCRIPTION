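Package: wavepls
Title: Oscillatory EEG Analysis with Morlet Wavelets and Inter-Site Phase Locking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-frequency analysis of epoched oddball EEG: complex Morlet
    wavelet decomposition of single trials, baseline-corrected evolutionary
    spectra, the inter-site phase-locking statistic (PLS) against a reference
    electrode, band/time-window region-of-interest extraction over a
    39-channel montage, and mixed repeated-measures ANOVA with
    Greenhouse-Geisser correction. Includes a synthetic oddball-EEG generator
    with known oscillatory power and von Mises phase coupling so that every
    analysis stage can be validated against ground truth, plus EDF and
    array-fixture readers and writers and a configuration-driven pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
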