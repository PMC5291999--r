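Package: footkin
Title: Multi-Segment Foot Kinematics and Static-to-Dynamic Root Model Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based six-segment foot kinematics for gait analysis:
    rigid-body pose estimation from marker clusters, Cardan x-y-z
    inter-segment angles, zero-phase Butterworth filtering, force-based
    gait event detection, and extraction of the standard rearfoot and
    hallux gait variables. Classifies the five Root-model static foot
    deformities (rearfoot varus, ankle equinus, hallux limitation, first
    ray and forefoot alignment), runs the subtalar-neutral pass-through
    analysis, and reproduces the normality-gated statistical battery
    comparing static deformity classes with dynamic compensations. A
    synthetic gait-cohort generator with known ground truth makes every
    stage testable without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
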