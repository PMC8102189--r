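Package: cardioipw
Title: Propensity-Weighted Analysis of Cardiac Function in Observational AML Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective cardio-oncology cohort analysis: propensity-score
    estimation by logistic regression, inverse-probability-of-treatment weighting with
    trimming of extreme propensity scores and weight truncation, standardized-mean-difference
    balance diagnostics with effective sample sizes, weighted and unweighted comparison of
    left-ventricular ejection fraction trajectories at discrete timepoints, Table-1-style
    descriptive group comparisons, Kaplan-Meier and log-rank survival analysis with
    reverse-Kaplan-Meier follow-up, a semiquantitative sarcomere-organization grading
    scheme, and a synthetic confounded-cohort generator so the full pipeline can be
    exercised and validated without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
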