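Package: proxinet
Title: Proximity-Sensor Contact Network Reconstruction for a Preschool RFID Deployment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for wearable RFID proximity-sensor deployments in
    a preschool setting: reading and writing half-day beacon-log files, initial
    cleaning (incident removal, fragment merging, session clipping), a
    four-stage artifact-removal pipeline driven by sliding-window RSSI
    statistics, reconstruction of temporal contact networks from mutual
    "handshake" observations via logistic state classification with naive
    gap-merging or hidden Markov smoothing, segmentation of half-days into
    free-time and class-time periods from the smoothed inter/intra-class
    interaction ratio, event annotation, and summary network statistics.
    Includes a deployment simulator that generates beacon logs with known
    ground truth (contact events, schedules, injected artifacts) so that every
    stage can be validated without access-restricted field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
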