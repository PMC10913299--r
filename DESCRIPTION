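Package: startpheno
Title: Simulation and Analysis of Multi-Task Tablet-Based Autism Screening Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-task touchscreen screening batteries for
    autism and related neurodevelopmental conditions in young children, of the
    kind delivered by non-specialist health workers on a tablet (the START
    battery design: preferential looking, social button choice, sensory wheel,
    motor following, bubble popping, colouring, a 14-item caregiver
    questionnaire and coded caregiver-child interaction). Provides a calibrated
    synthetic-cohort simulator that emits raw per-child session streams for
    three groups (typically developing, autism spectrum, intellectual
    disability), per-task feature extraction under pre-set inclusion filters
    (trajectory RMSE, spectral frequency gain, jerk, gaze proportions, outline
    crossings, touch force and offsets), group-comparison statistics (one-way
    ANOVA from raw data or printed summary statistics, robust alternatives,
    partial eta-squared, Bonferroni post hocs, chi-square, two-way mixed
    absolute-agreement single-measure ICC) and repeated cross-validated
    multi-class classification with feature-block subset search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    glmnet,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
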