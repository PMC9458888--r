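Package: diaryreact
Title: Bayesian Censored Skew-Normal Multilevel Models for Daily-Diary
    Stress Reactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for intensive-longitudinal (daily diary) analyses of
    affective reactivity to daily stressors, with awareness of age-related
    change (AARC) as a within- and between-person moderator. Implements
    scale scoring for daily AARC, affect (SPANE), subjective vitality and
    stressor-severity indices; within/between-person disaggregation and
    long-form standardization; two-level random-intercept regression with
    left/right-censored normal and censored skew-normal likelihoods fit by
    a built-in No-U-Turn sampler with compiled gradients; highest-density
    intervals and dual region-of-practical-equivalence (ROPE) decision
    rules; posterior probing of interaction effects (reactivity slopes,
    difference-of-differences, quadratic stress curves); approximate
    leave-one-out model comparison via Pareto-smoothed importance
    sampling; and a calibrated synthetic diary-data generator that
    provides ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
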