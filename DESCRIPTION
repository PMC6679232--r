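Package: surfprofiler
Title: Surf Session Profiling from Smartphone Inertial and GPS Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and characterises surf-session events (wave rides, paddling,
    sprint paddling, duck dives, laying and sitting on the board) from raw
    smartphone sensor streams: a gradient-descent quaternion orientation filter
    fuses accelerometer, gyroscope and magnetometer readings and separates
    gravity from linear acceleration; a sliding-window rule engine fuses the
    inertial features with GPS speed to detect waves and classify stances; and
    laying periods are sub-segmented with Lomb-Scargle periodograms of the
    gravity signals to distinguish paddle, sprint paddle, dive and idle laying.
    Includes a seeded synthetic-session generator with ground-truth labels,
    sample- and event-level evaluation reports, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
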