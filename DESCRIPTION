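Package: mousetrackr
Title: Multi-Animal Video Tracking with RFID Identity Assignment and
    Home-Cage Behavior Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis pipeline for video-plus-RFID rodent tracking:
    a modified SORT tracker (Kalman-predicted boxes, Hungarian IOU
    association, coasting through detection failures and re-association of
    reborn tracks), RFID-to-track identity matching with retroactive
    correction bounded by proximity events, a background-subtraction motion
    detector, trajectory analytics (Ramer-Douglas-Peucker simplification,
    kinematics, turn angles, center occupancy, social-interaction episodes),
    dynamic-time-warping trajectory-similarity scores, MOTA/coverage
    tracking evaluation, and a synthetic multi-mouse arena simulator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
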