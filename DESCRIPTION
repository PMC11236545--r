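Package: meshpain
Title: Pain Detection from 3D Facial Mesh Time Series in Sedated Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting the presence of pain from depth-camera facial
    mesh recordings of deeply sedated intensive-care patients. Converts
    1,220-point 3D facial mesh streams into Action-Unit (FACS) feature time
    series via two distance-based strategies (mean point-to-nose-anchor
    distance and mean point-to-centroid distance), applies gap-aware
    preprocessing (readjustment removal, short-segment pruning, moving-average
    smoothing), summarises each annotation window with six interval statistics
    per feature including a duration-normalised "area around the mean"
    computed by the trapezoidal rule with gap exclusion, aligns the
    descriptors with Behavioral Pain Scale (BPS) facial sub-scores, and
    trains and evaluates a k-nearest-neighbour classifier under
    leave-one-subject-out cross-validation with balancing undersampling,
    F1-tuned hyperparameters, stratified-bootstrap AUC confidence intervals
    and operating-point selection. A synthetic mesh-session generator with
    controllable pain structure, acquisition jitter, dropouts and
    readjustment artifacts makes the whole chain testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
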