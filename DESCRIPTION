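Package: weberstair
Title: Weber Fraction Estimation and Analysis for Adaptive Dot-Comparison Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-up/one-down staircase dot-comparison
    experiments used to measure approximate number sense (ANS) acuity. Provides
    the Gaussian ANS psychometric model, maximum-likelihood and weak-prior (MAP)
    estimation of per-session Weber fractions, a faithful simulator of the
    12-level staircase task (practice gate, trial decks, stimulus geometry),
    a synthetic-cohort generator calibrated to a field study of education and
    task-presentation effects, and the regression stage: per-task least squares,
    a sum-coded random-intercept mixed model, within-subject difference-score
    models, and parameter-recovery harnesses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
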