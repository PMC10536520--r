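Package: mgceye
Title: Quantitative Ptosis and Ocular-Misalignment Metrics from Telehealth Video Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid eye-segmentation pipeline for the ocular exercises of the
    Myasthenia Gravis Core Examination performed over telehealth video. Coarse
    per-eye regions of interest from a 68-point facial landmark model are
    refined by local, hypothesis-validated interface segmentation (two-cluster
    intensity partition cross-checked by an open active contour), from which
    per-frame eyelid and iris positions, a barycentric ocular-misalignment
    coordinate, and filtered one-minute time series with trend estimates are
    computed. Includes a ground-truthed synthetic eye-image generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
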