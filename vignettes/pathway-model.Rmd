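---
title: "A rule-driven management pathway for type 2 diabetes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rule-driven management pathway for type 2 diabetes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabpath)
```

## The management model

`diabpath` implements a closed-loop management pathway for type 2 diabetes
mellitus (T2DM) and comorbid hypertension, organized around nine management
tasks in three sets:

* **regular management** — risk assessment, hierarchical management,
  self-monitoring, regular follow-up;
* **pathway variation** — abnormal attention (warning-driven intervention)
  and compliance management;
* **self-management support** — medication guidance, lifestyle guidance,
  health education.

A patient enters the pathway on diagnosis, receives a cardiovascular risk
assessment, and is assigned a **hierarchical management level** from
glycemic control:

* routine **level 1** — stable blood glucose: all available readings within
  control target (fasting blood glucose, FBG, at most 7.0 mmol/L; 2-hour
  postprandial blood glucose, PBG, at most 10.0 mmol/L);
* routine **level 2** — above target but fasting glucose at most
  11.1 mmol/L ("unsatisfactory" or substandard control);
* intensive **level 3** — fasting glucose *strictly above* 11.1 mmol/L.

The 11.1 mmol/L bound and the strictness of the inequality are the load-bearing
constants of the stratification; the level-1/level-2 split uses the control
targets of the Chinese T2DM prevention and control guidelines, since
"stable" and "unsatisfactory" are qualitative terms. All thresholds live in
`default_config()` and are configurable; none is hard-coded.

The patient's condition is re-evaluated every 30 days on trailing 30-day
mean readings, and the level is adjusted dynamically: an **upgrade**
(toward intensive care) takes effect immediately — also same-day when a
single fasting reading crosses the intensive bound — while a **downgrade**
requires two consecutive in-target evaluations. The hysteresis is a design
choice against level oscillation near a threshold; the asymmetry is
deliberate (escalation is a safety action, de-escalation is not urgent).

Regular follow-up is scheduled at the level's interval: every 90 days for
level 1 and monthly (30 days) for levels 2 and 3, so a substandard patient
accrues exactly 3 regular follow-ups per 90-day management cycle. A
"month" is fixed at 30 days and a management cycle at 90 days to make
schedules deterministic.

## Knowledge representation and inference

Management knowledge is a declarative rule base in the style of the
Semantic Web Rule Language: condition→action rules over ground patient
facts, grouped into ten knowledge modules (diagnosis patterns, risk
assessment, control objectives, hierarchical management, self-monitoring,
regular follow-up, abnormal attention, medication guidance, lifestyle
guidance, compliance management), each rule labelled with its provenance
(clinical expert experience, medical guidelines, or both). The shipped
default base (`default_rulebase()`) is a representative authored set
covering all ten modules; rule files are JSON, validated against a
predicate registry, and numeric operands may be written as
`{"ref": "targets.intensive_fbg"}` so that clinical thresholds stay in
configuration rather than rule text.

Inference (`infer()`) is monotone forward chaining to a fixpoint: each rule
fires at most once on the ground facts, derived facts are only added, and
termination is guaranteed (a pass bound of 1000 guards against malformed
inputs). Numeric comparisons are exact on the decimal values as read — no
epsilon — which is what makes the strict `> 11.1` boundary testable to the
grid resolution.

Two kinds of derived predicates exist. Multi-valued predicates (warnings,
plan items, risk factors) accumulate with deduplication. Single-valued
predicates (management level, follow-up interval) admit one value;
conflicting assertions resolve by highest priority, then lexicographically
smallest rule id. Internally this is realized as *replace-if-stronger*: a
later-firing rule with higher rank overrides a weaker earlier assertion.
Facts already derived from an overridden value are not retracted — a
deliberate simplification; the shipped base is written so that nothing
chains off a value that can be overridden, and the property tests check
order-independence of the fixpoint on permuted rule lists. Every firing is
recorded in a trace, and `explain()` reconstructs the minimal derivation
chain of any assertion (root causes first), which is what makes plan items
and level assignments auditable.

## Pathway variation

Abnormal attention (`detect_warnings()`) classifies a day's self-monitoring
records against configurable alert bounds chosen from the hypoglycemia /
severe-hyperglycemia and urgent-blood-pressure conventions of the
guidelines the pathway is built on:

| warning | default bounds | units |
|---|---|---|
| BG_WARNING | any glucose < 3.9 or ≥ 16.7; fasting ≥ 13.9 | mmol/L |
| BP_WARNING | SBP ≥ 160 or < 90; DBP ≥ 100 | mmHg |
| HR_WARNING | < 50 or > 120 | bpm |
| DISORDER_WARNING | coded symptom severity ≥ 2 | grade 1–3 |

Warnings are debounced to one per (patient, type, day), and each unresolved
warning draws a physician follow-up the next day. Repeated warnings on
later days draw repeated follow-ups; regular and abnormal events are never
merged.

Compliance management computes the completion rate of scheduled tasks over
a trailing 7-day window (vacuously 1 when nothing was scheduled); a rate
below 0.5 flags low compliance and draws a motivational follow-up, at most
once per window. Every emitted follow-up event carries exactly one of the
three categories — regular, abnormal attention, compliance — which is the
partition the retrospective accounting relies on.

## Care plans

`build_patient_plan()` derives the patient self-management plan from the
rule base with the assigned level seeded in: a blood-glucose profile on
1 / 3 / 7 days per week for levels 1 / 2 / 3 (the frequencies are
guideline-informed configuration, not printed constants), daily home blood
pressure if and only if the patient has comorbid hypertension, plus
medication-class, lifestyle and education items. Medication knowledge is
intentionally shallow — class-level suggestions traceable to rules, never
dosing — and mutually exclusive suggestions firing together are reported as
a rule-base defect. Health-education content ships as a static topic list
keyed by level and comorbidity (education is one of the nine tasks but not
a rule module), so those items carry a `builtin:` source tag instead of a
rule id. `build_physician_plan()` carries the regular follow-up interval
and one intervention item per open warning.

## The synthetic cohort

`simulate_cohort()` generates the study conditions every statistical test
runs under: 272 patients; 42.6% with comorbid hypertension; 65.1% abnormal
initial blood glucose; 69.8% abnormal initial blood pressure among
hypertensive patients; 54% male; adult age ~ N(58.24, 9.81²) years; small
adolescent (2.6%) and disability (0.7%) special groups; a 90-day horizon.
Each patient's entire stream is drawn from a generator keyed by
(seed, patient id), so enlarging the cohort never perturbs existing
patients.

Baselines are normal/abnormal mixtures (e.g. fasting glucose
N(6.1, 0.45²) clipped to [4.5, 6.9] mmol/L when normal, N(9.6, 1.6²)
clipped to [7.1, 16] when abnormal; systolic pressure N(125, 7²) vs
N(155, 10²) mmHg), values chosen once as clinically plausible for a managed
Chinese T2DM cohort. Each completed physician follow-up — of any category —
lowers the underlying trajectory by the per-follow-up effect (defaults:
FBG 0.8, PBG 1.0 mmol/L; SBP 6, DBP 5 mmHg), floored at plausible minima
(FBG 4.8 mmol/L, SBP 108 mmHg, ...); the effect sizes are tuned to the
order of magnitude of published 3-month management deltas, not claimed
reproductions of them. Measurement noise is homoscedastic per kind
(FBG 0.6, PBG 1.1 mmol/L; SBP 7, DBP 5 mmHg; HR 6 bpm). Daily adherence is
patient-specific, Beta(3.5, 1.5) (mean 0.7 with a long low-adherence tail —
the heterogeneity is what makes compliance management non-trivial), and
rises by +0.2 (capped at 0.95) after each compliance follow-up. Patients
log a daily medication task, glucose-profile tasks on plan days, and daily
blood pressure when hypertensive; symptoms arrive as rare (1%/day) coded
reports.

Two execution modes exist on purpose. The **open-loop** generator
(`simulate_cohort()`) uses a simplified internal intervention process —
level from baseline thresholds, regular schedule, next-day abnormal
response, weekly compliance check — and is fast enough for repeated-seed
statistical tests. The **closed loop** (`run_closed_loop()`) co-simulates
day by day through the engine's `step()`, because measurements must respond
to the engine's own events; the physician is modelled as an event consumer
who completes every follow-up immediately. What the simulator does *not*
emulate: real measurement cadence (records follow plan frequencies),
dropout and loss to follow-up, pharmacokinetics, or seasonal/behavioural
drift — so passing tests demonstrate the engine's contracts and the
direction of intervention effects, not clinical effect sizes in real
cohorts.

## Retrospective analytics

`summarize_followups()` reproduces the follow-up accounting (counts and
percentage shares by category, warning-type breakdown within abnormal
attention); `mean_followups_per_patient()` the per-patient means;
`classify_intervention_level()` the high / medium / low partition at more
than 3 / exactly 3 / fewer than 3 visits; `monthly_trend()` bins readings
into 30-day months from each patient's cycle start, takes per-patient
monthly means as primary (the pooled per-reading mean is reported
alongside, since either averaging convention is defensible), and compares
month 1 against month 3 with a paired two-tailed t-test on patients present
in both months (Welch is deliberately not used). `compare_counts()` wraps
the standard uncorrected chi-square test. Percentages are rounded half-up
to one decimal and means to two, matching report-style printing.

## Numerical and testing choices

* Dates are day-granular for scheduling; measurement ordering uses the full
  timestamp, ties keep the last record read (with a logged warning).
* `step()` is idempotent for a repeated call on the same date and rejects
  dates moving backwards; identical replays yield byte-identical event
  logs.
* Degenerate inputs degrade softly: no glucose facts at assessment give
  routine level 2 with an `insufficient_data` flag; an empty record set
  yields a profile-only fact base; an empty rule base makes inference the
  identity.
* The parameter-recovery check regresses each patient's month-1 minus
  month-3 glucose decline on the *exposure-weighted* follow-up count (the
  difference in mean follow-ups-before-reading between the two windows),
  whose slope is exactly the per-follow-up effect in expectation; a raw
  count would be attenuated by follow-ups at the window edges. Patients
  whose designed trajectory is floor-censored (decided from baseline and
  follow-up count, not from outcomes) are excluded. Recovery is asserted
  within 2 standard errors at n = 272.
* Test problem sizes are chosen to keep the default suite quick while
  preserving power: brute-force oracle equivalence on rule bases of at most
  8 rules, composition and recovery at the full n = 272, directional
  fidelity over 20 seeds, and one full 272-patient, 90-day closed-loop
  replay.

## Known limitations

The rule base is representative, not a reproduction of any deployed
clinical rule set; per-rule clinical fidelity is out of scope, only the
module taxonomy and the engine's behavior are contracted. The engine holds
one patient's state at a time (cohort replay is a loop, not a joint
simulation); there is no cross-patient resource model for physician time.
Fasting and postprandial glucose carry their meal context as a convention
only — the package stores and never validates it — and measurement units
are implied by kind, with out-of-convention units rejected rather than
converted.
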