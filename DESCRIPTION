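Package: dailygait
Title: Daily-Life Gait and Turning Analysis with Fall-Risk Model Selection
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing week-long, free-living recordings from foot- and
    lumbar-worn inertial sensors in people with Parkinson's disease. Implements a
    time-domain gait pipeline (step detection from foot pitch angular velocity,
    gait-bout assembly with a 2.5 s inter-step gap rule and a 3 s / 3 step bout
    filter, stride segmentation, straight-walking selection, and lumbar-based turn
    detection with a 40 degree amplitude rule), reduces a subject-week to a
    52-measure digital gait catalog in four domains (Lower Body, Lower Trunk,
    Turning, Variability), and screens measure combinations for discriminating
    future fallers from non-fallers by exhaustive best-subsets logistic regression
    with BIC followed by empirical-AUC ranking. A two-tier synthetic-data module
    (ground-truth event timelines plus a physics-consistent signal renderer)
    generates cohorts with known stride, turn and fall-outcome structure so every
    stage of the pipeline can be verified without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    data.table,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
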