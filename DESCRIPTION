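Package: stimloop
Title: Closed-Loop Cutaneous Stimulation: Virtual Rig, Calibration and
    Behavioral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-top re-implementation of a closed-loop system for precision
    cutaneous stimulation of freely moving mice.  Provides a virtual rig
    (gait-realistic keypoint simulator, rendered grayscale frames, steering
    optics with nonlinear distortion, processing/actuation latency models),
    pixel-to-voltage calibration by two-dimensional polynomial surface
    fitting, stillness-triggered stimulation with refractory accounting and
    hit/confusion adjudication, random-access multi-chamber scheduling from
    per-chamber motion energy, an alternation-maze task engine with one-way
    doors and Euler-tour condition ordering, and a post-hoc behavioral
    analysis suite (trajectory preprocessing, speed categories, stance/swing
    gait segmentation, motion-energy and pose-based response latency,
    heading coherence, Gaussian-mixture movement-state clustering and paired
    pre/post state-dependence statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    zoo,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
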