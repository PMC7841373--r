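Package: swimseg
Title: Macro-Micro Swimming Analysis from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based analysis of swimming training sessions recorded with
    inertial measurement units (3D accelerometer and gyroscope) worn on the
    sacrum, head, wrists and shanks. Macro analysis detects swimming bouts,
    laps (approximate turns) and the swimming technique of each lap; micro
    analysis segments every lap into wall push-off, glide, strokes
    preparation, swimming and turn phases by detecting the beginning of each
    phase. Includes the underlying signal primitives (zero-phase Butterworth
    filtering, extremum and sharp-change detection, envelopes, PCA, power
    spectra, empirical mode decomposition and Hilbert-Huang instantaneous
    energy), validation metrics (sensitivity, precision, accuracy, event
    error statistics, phase-duration errors, Bland-Altman agreement,
    threshold sensitivity sweeps) and a synthetic-session simulator that
    provides exact ground truth for every detector.
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
    yaml,
    optparse
Config/testthat/edition: 3
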