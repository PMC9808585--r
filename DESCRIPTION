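Package: diabpath
Title: Rule-Driven Management Pathway Engine for Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An executable, rule-driven decision-support engine for the
    closed-loop management of type 2 diabetes mellitus and comorbid
    hypertension. Patients are stratified into hierarchical management
    levels from glycemic control (routine level 1, routine level 2,
    intensive level 3 for fasting glucose above 11.1 mmol/L), regular
    follow-up is scheduled by level, abnormal self-monitoring data raise
    warnings that trigger next-day physician attention, and low task
    compliance triggers motivational follow-up. Management knowledge is a
    declarative, provenance-labelled condition-action rule base evaluated
    by a forward-chaining inference engine with explanation traces.
    Includes a synthetic cohort simulator with intervention-responsive
    glucose and blood-pressure trajectories and retrospective analytics
    (follow-up accounting, intervention-level classification, monthly
    trends with paired t-tests, chi-square comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
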