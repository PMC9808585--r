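rb <- default_rulebase()
cfg <- default_config()

test_that("patient plans carry level-appropriate monitoring and comorbidity gates", {
  prof3 <- mk_profile(htn = TRUE, age = 62)
  facts3 <- build_factbase(prof3,
                           rbind(mk_meas("pt1", "FBG", 12.5),
                                 mk_meas("pt1", "SBP", 150),
                                 mk_meas("pt1", "DBP", 92)),
                           NULL, D0, cfg)
  plan3 <- build_patient_plan(prof3, 3, facts3, rb, cfg)
  expect_equal(plan3$role, "patient")
  bg <- Filter(function(it) it$task == "self_monitoring" &&
                 grepl("glucose", it$content), plan3$items)
  expect_length(bg, 1)
  expect_equal(bg[[1]]$frequency_per_week, 7)  # daily at intensive level
  bp <- Filter(function(it) grepl("blood pressure", it$content) &&
                 it$task == "self_monitoring", plan3$items)
  expect_length(bp, 1)
  expect_equal(bp[[1]]$frequency_per_week, 7)

  # level 1, diabetes only: weekly glucose profile, no BP monitoring item
  prof1 <- mk_profile()
  facts1 <- build_factbase(prof1, rbind(mk_meas("pt1", "FBG", 6.0),
                                        mk_meas("pt1", "PBG", 8.0)),
                           NULL, D0, cfg)
  plan1 <- build_patient_plan(prof1, 1, facts1, rb, cfg)
  bg1 <- Filter(function(it) it$task == "self_monitoring" &&
                  grepl("glucose", it$content), plan1$items)
  expect_equal(bg1[[1]]$frequency_per_week, 1)
  expect_length(Filter(function(it) grepl("blood pressure", it$content),
                       plan1$items), 0)
  # only patient-role tasks appear
  expect_true(all(vapply(plan1$items, `[[`, "", "task") %in%
                    c("self_monitoring", "medication_guidance",
                      "lifestyle_guidance", "health_education")))
})

test_that("plan generation is deterministic", {
  prof <- mk_profile(htn = TRUE, bmi = 30, smoker = TRUE)
  facts <- build_factbase(prof, mk_meas("pt1", "FBG", 9.0), NULL, D0, cfg)
  p1 <- build_patient_plan(prof, 2, facts, rb, cfg)
  p2 <- build_patient_plan(prof, 2, facts, rb, cfg)
  expect_identical(p1, p2)
})

test_that("physician plans schedule by level and append warning interventions", {
  p2 <- build_physician_plan(2, cfg)
  expect_equal(p2$items[[1]]$task, "regular_follow_up")
  expect_equal(p2$items[[1]]$interval_days, 30L)  # monthly for substandard
  p1 <- build_physician_plan(1, cfg)
  expect_equal(p1$items[[1]]$interval_days, 90L)

  w <- detect_warnings(mk_meas("pt1", "SBP", 172, day = 2), cfg)
  p <- build_physician_plan(2, cfg, open_warnings = w)
  bp_items <- Filter(function(it) it$task == "abnormal_attention", p$items)
  expect_length(bp_items, 1)
  expect_match(bp_items[[1]]$content, "pressure")
})

test_that("medication guidance is rule-traceable, class-level and context-driven", {
  # intensive-level facts fire the intensification item
  facts3 <- mk_facts(latest_FBG = 12.5)
  items3 <- medication_guidance(facts3, rb)
  contents <- vapply(items3, `[[`, "", "content")
  expect_true(any(grepl("intensification", contents)))
  expect_true(all(vapply(items3, `[[`, "", "source_rule") %in%
                    vapply(rb, `[[`, "", "rule_id")))

  # in-target facts fire nothing
  expect_length(medication_guidance(mk_facts(latest_FBG = 6.0,
                                             latest_PBG = 8.0), rb), 0)

  # uncontrolled comorbid blood pressure draws an antihypertensive review
  fh <- mk_facts(latest_FBG = 8.0, has_hypertension = TRUE,
                 latest_SBP = 155, latest_DBP = 88)
  ch <- vapply(medication_guidance(fh, rb), `[[`, "", "content")
  expect_true(any(grepl("antihypertensive", ch)))
})

test_that("every rule-derived plan item traces back through explain()", {
  prof <- mk_profile(htn = TRUE, bmi = 30)
  facts <- build_factbase(prof, rbind(mk_meas("pt1", "FBG", 12.0),
                                      mk_meas("pt1", "SBP", 150),
                                      mk_meas("pt1", "DBP", 95)),
                          NULL, D0, cfg)
  res <- infer(facts, rb)
  plan <- build_patient_plan(prof, 3, facts, rb, cfg)
  rule_ids <- vapply(rb, `[[`, "", "rule_id")
  for (it in plan$items) {
    if (identical(it$source_rule, "builtin:health_education")) next
    expect_true(it$source_rule %in% rule_ids)
  }
  # the plan_item predicate itself is explainable from the trace
  chain <- explain("plan_item", res,
                   value = list(task = "medication_guidance",
                                content = "therapy intensification review",
                                frequency_per_week = 1))
  expect_gt(length(chain), 0)
})

test_that("contradictory exclusive medication firings are reported as defects", {
  rules <- list(
    mk_rule("MX-1", list(atom("latest_FBG", ">", 7)),
            list(act("plan_item",
                     list(task = "medication_guidance",
                          content = "therapy intensification review",
                          frequency_per_week = 1))),
            module = "medication_guidance", provenance = "guideline"),
    mk_rule("MX-2", list(atom("latest_FBG", ">", 7)),
            list(act("plan_item",
                     list(task = "medication_guidance",
                          content = "therapy de-escalation review",
                          frequency_per_week = 1))),
            module = "medication_guidance", provenance = "guideline")
  )
  expect_error(medication_guidance(mk_facts(latest_FBG = 9),
                                   mk_rulebase(rules)),
               "rule-base defect")
})
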