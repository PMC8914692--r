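Package: sleepose
Title: Contact-Free Sleep Posture Monitoring from Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contact-free, camera-based monitoring of sleep posture.
    A sample-based background-subtraction stage (ViBe) detects body movement in
    bedroom video and gates a two-stage multi-task detector that localizes the
    sleeper's head and upper body and classifies each region into one of four
    clinical postures (supine, prone, left side, right side). Per-frame
    detections are aggregated into a posture timeline from which four
    posture-focused sleep-quality indicators are computed (posture shifts per
    hour, long-posture rate, average posture duration, and turning-based sleep
    efficiency), together with a circular night-synopsis diagram. A seeded
    synthetic-scene generator renders annotated bed scenes, motion videos, and
    posture timelines so the whole pipeline can be trained and validated
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
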