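Package: ovucal
Title: Calendar-Based Ovulation Prediction from Self-Tracked Menstrual Cycle Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives menstrual cycle, follicular phase, and luteal phase
    lengths from dated event logs of menstruation onsets and ovulation
    records; fits panel linear models (pooled ordinary least squares, the
    least-squares-dummy-variables within estimator, and random-effect
    generalized least squares under compound symmetry) relating phase
    lengths to trailing mean cycle length, with a Hausman specification
    test; and compares three calendar-based predictors of the next
    ovulation date (Ogino, half-cycle-length, and an optimized linear
    predictor) at allowable errors of 0, 1, and 2 days. Includes a seeded
    synthetic event-log generator emulating the structure of large
    cycle-tracking app cohorts, and an end-to-end pipeline producing
    summary tables, correlation and per-k fit reports, and accuracy
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
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
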