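Package: hdebm
Title: Event-Based Modelling of Biomarker Progression in Huntington's
    Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-cohort event-based modelling (EBM) of imaging and
    clinical biomarker progression in Huntington's disease. Fits
    two-component kernel-density-estimate mixture models separating
    healthy from abnormal biomarker distributions, infers the most
    likely order in which biomarkers become abnormal by greedy ascent
    and Markov chain Monte Carlo over event permutations, stages
    individual subject-visits by maximum-likelihood and expected stage,
    compares event sequences across cohorts with Kendall's tau, and
    models progression through stages as a function of age and CAG
    repeat length with polynomial mixed-effects regression. Includes a
    synthetic multi-cohort data generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
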