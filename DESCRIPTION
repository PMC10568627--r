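Package: pupilgca
Title: Growth-Curve Analysis of Event-Related Pupillometry for Listening Effort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for event-related pupillometry studies of
    listening effort in speech-in-noise experiments. Reads trial-epoched pupil
    recordings in a documented CSV dialect, applies the standard calibration
    chain (downsampling, area-to-diameter conversion, artifact detection,
    run-wise linear interpolation, baseline normalization to percent
    event-related pupil dilation, moving-average smoothing), applies trial- and
    participant-level exclusion rules, scores keyword intelligibility with the
    rationalized arcsine transform, and models ERPD time courses with growth
    curve analysis: orthogonal cubic polynomial bases inside linear
    mixed-effects models, likelihood-ratio model selection with a documented
    non-convergence fallback ladder, and Tukey-adjusted pairwise contrasts.
    Includes repeated-measures correlation between intelligibility and
    subjective effort ratings, and a synthetic-experiment generator with known
    ground truth (condition-dependent cubic dilation curves, participant random
    effects, AR(1) noise, blink dropouts, binomial keyword scores driven by
    psychometric functions of SNR) so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
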