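Package: strokehar
Title: Activity Recognition for Hemiparetic Stroke Patients from Wearable IMU Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline for classifying upper-limb movements of
    hemiparetic stroke patients and non-disabled individuals from body-worn
    inertial measurement units (five sensors, accelerometer/gyroscope/
    magnetometer). Provides readers and writers for a CSV recording dialect
    with segment annotations and participant exclusion rules, signal
    preprocessing (zero-centering, channel selection, left/right sensor
    swapping, linear interpolation to a fixed length, fixed-count sliding
    windows), an energy-ratio movement-asymmetry score, axis-rotation data
    augmentation, a 1D convolutional network classifier trained with AdamW,
    leave-one-subject-out evaluation across training-group conditions with
    per-participant per-class F1 reporting and confusion matrices, and a
    synthetic IMU-movement generator so the whole pipeline is testable
    without any recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
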