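Package: wearweek
Title: Wearable Step and Activity Processing for Pre/Post Natural Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes minute-level consumer wearable exports (step counts and
    motion intensity) into analysis-ready weekly physical-activity outcomes for
    interrupted pre/post designs: epoch-based nonwear detection, valid-day and
    valid-week filtering, weekday/weekend-weighted weekly aggregation,
    cadence-bout detection of moderate-to-vigorous physical activity minutes,
    participant inclusion rules, and linear mixed-effects pre/post comparison
    with estimated marginal means. Includes a synthetic-cohort generator with
    ground truth so every pipeline stage and both model families can be
    validated without access to raw device data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
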