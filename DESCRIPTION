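Package: stresscomp
Title: Compositional Multilevel Analysis of 24-Hour Physical Behavior and
    Daily Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking device-based 24-hour physical-behavior
    compositions (sleep, sedentary behavior, light and moderate-to-vigorous
    physical activity) to daily self-perceived stress and coping
    self-efficacy from ambulatory-assessment studies. Implements pivot
    isometric log-ratio coordinates for the four-part day under four named
    rotations, multiplicative and EM-based replacement of below-detection
    zeros, within-person centering, two-level mixed models with
    random-slope selection and intraclass correlations, compositional
    isotemporal substitution (time-reallocation) prediction with cluster
    bootstrap confidence intervals, and a calibrated synthetic-cohort
    generator with the between/within structure such studies assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
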