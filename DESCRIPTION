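Package: gtcsdetect
Title: Wearable Accelerometry Detection of Generalized Tonic-Clonic Seizures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects generalized tonic-clonic seizures (GTCS) in dogs from
    wearable three-axis accelerometer recordings. Raw 50 Hz traces are reduced
    to eight per-second parameters (mean and coefficient of variation of each
    axis and of the resultant force), cut into sliding 9-s epochs, and
    classified by comparing Mahalanobis distances to two reference models: a
    seizure reference (RDE) and a daily-activity reference (RDNE) built from
    labelled recordings. Includes a streaming detector with refractory logic,
    a seeded synthetic-accelerometry simulator covering fifteen canine daily
    activities, tonic-clonic seizure bursts and sensor-displacement artifacts,
    and event- and epoch-level detector evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
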