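Package: gazecog
Title: Looking-Based Infant Visual Cognition and In-Home Air Quality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline linking infant preferential-looking change-detection
    data to in-home particulate air quality. Scores gaze streams from
    eye-tracking or hand-coded video into first-look classes, change
    preference, gaze shift rate and early-window looking measures; filters
    and downsamples 10-second air-quality-index logs, fits a diurnal-by-date
    tensor-smooth exposure model with shrunken household intercepts, and
    converts between PM2.5 concentration and the US Air Quality Index;
    builds baseline and exposure-augmented linear mixed-effects models with
    forward interaction selection, Satterthwaite p-values, type-3 Wald tests
    and partial eta-squared effect sizes. A seeded synthetic-data generator
    emulates households, device logs, gaze streams and standardized
    assessment scores with a ground-truth ledger so every stage is testable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
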