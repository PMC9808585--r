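# diabpath

An executable, rule-driven decision-support engine for the closed-loop
management of type 2 diabetes mellitus (T2DM) and comorbid hypertension —
the kind of pathway logic that sits behind a telehealth system connecting
community physicians with self-monitoring patients. It is aimed at digital
health researchers and engineers who need a transparent, testable reference
implementation of hierarchical chronic-disease management rather than a
black-box service.

## The model

Management is organized as nine tasks in three sets (regular management,
pathway variation, self-management support). The load-bearing statistic is
the **hierarchical management level**, assigned from glycemic control:

* routine level 1 — stable: FBG ≤ 7.0 mmol/L and PBG ≤ 10.0 mmol/L,
* routine level 2 — above target but FBG ≤ 11.1 mmol/L (substandard),
* intensive level 3 — FBG > 11.1 mmol/L (strict inequality),

where FBG / PBG are fasting and 2-hour postprandial blood glucose. Levels
drive everything downstream: regular follow-up every 90 days (level 1) or
monthly (levels 2–3, i.e. 3 follow-ups per 90-day cycle), self-monitoring
frequency (1 / 3 / 7 days per week), and re-evaluation every 30 days on
trailing 30-day means with immediate upgrades and hysteretic downgrades.
Pathway variation adds abnormal-attention warnings (BG / BP / heart-rate /
symptom bounds, e.g. any glucose < 3.9 mmol/L or SBP ≥ 160 mmHg) that draw
a physician follow-up the next day, and compliance management (task
completion rate < 0.5 over 7 days) that draws a motivational follow-up.

The knowledge itself is a declarative, provenance-labelled condition→action
rule base (SWRL-style, JSON on disk, thresholds referenced from
configuration) evaluated by a monotone forward-chaining engine with full
firing traces, so every derived assertion — a level, a warning, a plan
item — can be explained back to the rules and facts that produced it. A
synthetic cohort simulator reproduces the marginal composition of a managed
cohort (n = 272, 42.6% hypertensive, 65.1% abnormal initial glucose, age
58.24 ± 9.81 y) with intervention-responsive trajectories, and the
analytics module recomputes the retrospective accounting (follow-up shares,
intervention levels, monthly trends with paired t-tests, chi-square
comparisons).

## Worked example

```r
library(diabpath)
rules <- default_rulebase()
cfg   <- default_config()

prof <- patient_profile("P0001", "female", 63,
                        diseases = c("diabetes", "hypertension"),
                        enrollment_date = "2024-01-01", bmi = 29.4)
baseline <- measurement_table(rep("P0001", 3), c("FBG", "PBG", "SBP"),
                              c(12.5, 15.8, 152), rep("2024-01-01", 3))
state <- enroll(prof, baseline, rules, cfg)
state
#> <pathway_state> P0001 - level 3 | next regular follow-up 2024-01-31 | open warnings: 0
```

A fasting glucose of 12.5 mmol/L exceeds the 11.1 mmol/L bound, so the
patient enters intensive level 3 and the first regular follow-up lands 30
days after enrollment. The risk assessment rules flag `hypertension,
advanced_age, obesity` (risk level `high`), and the generated
self-management plan follows the level and comorbidity:

```r
fb <- build_factbase(prof, baseline, NULL, as.Date("2024-01-01"), cfg)
build_patient_plan(prof, state$level, fb, rules, cfg)
#> <care_plan> patient plan for P0001 (level 3) issued 2024-01-01 - 11 items
#>   [self_monitoring] blood glucose profile (fasting + postprandial) (7x/week)
#>   [self_monitoring] home blood pressure (7x/week)
#>   [medication_guidance] therapy intensification review (1x/week)
#>   ...
```

Daily glucose and blood-pressure monitoring appear because the level is 3
and the patient is hypertensive; the intensification item is traceable —
`explain("management_level", infer(fb, rules))` reports that rule `HM-01`
fired on `latest_FBG = 12.5`.

Simulating a cohort and replaying it through the closed loop:

```r
sim <- simulate_cohort(cohort_config(n_patients = 60, seed = 17))
cl  <- run_closed_loop(sim, rules, cfg)
summarize_followups(cl$events)
#> <followup_summary> 282 follow-up events
#>            category count share
#>             regular   130  46.1
#>  abnormal_attention   109  38.7
#>          compliance    43  15.2

monthly_trend(cl$measurements, "FBG")
#> <monthly_trend> FBG : per-patient monthly means 7.69 / 6.76 / 6.19 |
#>   delta (m1 - m3) 1.5 | paired t p = 5.42e-13
```

The shares say a third-to-half of physician contacts are variation-driven
rather than scheduled, and the trend says the cohort's mean fasting glucose
fell by 1.5 mmol/L from month 1 to month 3 under the default
per-follow-up intervention effects — the paired t-test confirms the decline
is not noise.

A thin command-line front end ships at `inst/scripts/diabpath`
(`validate-rules`, `simulate`, `run`, `analyze`, `plan`).

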