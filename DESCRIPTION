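Package: eqitools
Title: Analysis of Eccentric Quasi-Isometric Dynamometer Contractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing eccentric quasi-isometric (EQI) contractions
    recorded on an isokinetic dynamometer in isotonic mode. Segments raw
    angle/velocity/torque trials into contraction windows (onset at the first
    local maximum of the angle signal, offset at end of range of motion or at a
    sustained drop of torque below half the prescribed load), computes the
    contraction outcome variables (total time, torque impulse by trapezoid
    integration, mean angular velocity, range of motion, start and final
    angles) and maximal voluntary isometric contraction (MVIC) peaks, and fits
    the mixed repeated-measures ANOVA battery used for such designs
    (split-plot sums of squares, Mauchly sphericity test, Greenhouse-Geisser
    correction, Bonferroni post hoc tests, partial eta-squared, estimated
    marginal means, Welch t and average-SD Cohen's d). A mechanistic
    contraction simulator (force-length capacity, cumulative fatigue,
    quasi-static yield) generates dynamometer-realistic synthetic studies with
    ground-truth event logs so every pipeline stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    car,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
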