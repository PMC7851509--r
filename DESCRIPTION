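Package: trajcog
Title: Indoor Trajectory Mining for Cognitive Health Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns smart-home position-sensor event streams into cleaned,
    segmented indoor trajectories; encodes each trajectory as a pair of
    images (path geometry and section speed) plus baseline numeric and
    binary-grid features; classifies trajectories into cognitively healthy,
    mild cognitive impairment (MCI) or person-with-dementia (PwD) classes
    with a two-branch multilayer perceptron; and aggregates per-trajectory
    predictions into a long-term hypothesis of diagnosis by majority vote.
    Includes a seeded synthetic smart-home locomotion simulator so the full
    pipeline is testable without access to clinical sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    randomForest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
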