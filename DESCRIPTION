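Package: preimpact
Title: Pre-Impact Fall Detection from Wearable Inertial Sensor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting falls from body-worn inertial measurement
    unit (IMU) recordings before body-ground impact. Implements a
    threshold-based detector over acceleration magnitude, posture angles and
    integrated vertical velocity (with grid-search calibration), a
    40-feature sliding-window pipeline feeding a support vector machine, a
    convolutional-recurrent (Conv+LSTM) sequence classifier over raw
    9-channel windows, a semiautomatic fall-onset labelling assistant, and a
    file-level evaluation protocol reporting sensitivity, specificity and
    detection lead time. A seeded kinematic simulator of labelled falls and
    activities of daily living makes the full pipeline testable without
    access to recorded datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
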