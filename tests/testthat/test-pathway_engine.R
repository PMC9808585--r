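rb <- default_rulebase()
cfg <- default_config()

test_that("level assignment follows the strict 11.1 mmol/L intensive boundary", {
  expect_equal(assess_level(mk_facts(latest_FBG = 11.2), rb, cfg), 3L)
  expect_equal(assess_level(mk_facts(latest_FBG = 11.1), rb, cfg), 2L)
  expect_equal(assess_level(mk_facts(latest_FBG = 7.5, latest_PBG = 11.0),
                            rb, cfg), 2L)
  expect_equal(assess_level(mk_facts(latest_FBG = 6.0, latest_PBG = 8.0),
                            rb, cfg), 1L)
  # no glucose facts: routine level 2 with an insufficient-data flag
  lvl <- suppressMessages(assess_level(mk_facts(age = 50), rb, cfg))
  expect_equal(as.integer(lvl), 2L)
  expect_true(attr(lvl, "insufficient_data"))
})

test_that("level assignment is non-decreasing in fasting glucose", {
  grid <- seq(40L, 200L) / 10
  lvl <- vapply(grid, function(x)
    as.integer(assess_level(mk_facts(latest_FBG = x, latest_PBG = 9.0),
                            rb, cfg)), 0L)
  expect_true(all(diff(lvl) >= 0))
})

test_that("enrollment runs risk assessment, assigns a level and schedules follow-up", {
  prof <- mk_profile(htn = TRUE, age = 65)
  st <- enroll(prof, mk_meas("pt1", "FBG", 12.5), rb, cfg)
  expect_equal(st$level, 3L)
  expect_equal(st$next_regular_followup, D0 + 30)
  expect_equal(st$risk_level, "high")
  expect_true("hypertension" %in% st$risk_factors)

  st1 <- enroll(mk_profile(), rbind(mk_meas("pt1", "FBG", 6.0),
                                    mk_meas("pt1", "PBG", 8.0)), rb, cfg)
  expect_equal(st1$level, 1L)
  expect_equal(st1$next_regular_followup, D0 + 90)

  non_dm <- structure(list(patient_id = "x", sex = "male", age = 50,
                           diseases = "hypertension", enrollment_date = D0,
                           special_group = character(), bmi = NA_real_,
                           smoker = FALSE), class = "patient_profile")
  expect_error(enroll(non_dm, NULL, rb, cfg), "only patients with diabetes")
})

test_that("regular follow-up schedule conserves floor(horizon / interval)", {
  expect_length(schedule_regular_followups(2, D0, 90, cfg), 3)
  expect_equal(schedule_regular_followups(2, D0, 90, cfg),
               D0 + c(30, 60, 90))
  expect_length(schedule_regular_followups(1, D0, 90, cfg), 1)
  expect_length(schedule_regular_followups(3, D0, 0, cfg), 0)
  for (h in c(1, 29, 30, 31, 59, 89, 90, 91, 180, 365)) {
    for (lvl in 1:3) {
      iv <- cfg$followup_interval_days[[as.character(lvl)]]
      expect_length(schedule_regular_followups(lvl, D0, h, cfg),
                    floor(h / iv))
    }
  }
})

test_that("re-evaluation upgrades immediately but downgrades with hysteresis", {
  prof <- mk_profile()
  st <- enroll(prof, mk_meas("pt1", "FBG", 12.5), rb, cfg)
  expect_equal(st$level, 3L)
  # two consecutive in-target evaluations on 30-day means drop 3 -> 1
  st <- reevaluate(st, mk_meas("pt1", "FBG", 6.5, day = 25), D0 + 30, rb, cfg)
  expect_equal(st$level, 3L)
  expect_equal(st$downgrade_streak, 1L)
  st <- reevaluate(st, mk_meas("pt1", "FBG", 6.5, day = 55), D0 + 60, rb, cfg)
  expect_equal(st$level, 1L)
  expect_equal(nrow(st$level_history), 2L)

  # upgrade is immediate
  st1 <- enroll(prof, rbind(mk_meas("pt1", "FBG", 6.0),
                            mk_meas("pt1", "PBG", 8.0)), rb, cfg)
  st1 <- reevaluate(st1, mk_meas("pt1", "FBG", 12.0, day = 28), D0 + 30,
                    rb, cfg)
  expect_equal(st1$level, 3L)

  # no new data: unchanged, flag logged
  st2 <- enroll(prof, mk_meas("pt1", "FBG", 8.0), rb, cfg)
  expect_message(st2b <- reevaluate(st2, NULL, D0 + 40, rb, cfg),
                 "level unchanged")
  expect_equal(st2b$level, st2$level)
})

replay_patient <- function(fbg = 8.0, pbg = 11.5, days = 1:90,
                           adherent = TRUE) {
  prof <- mk_profile()
  st <- enroll(prof, rbind(mk_meas("pt1", "FBG", fbg),
                           mk_meas("pt1", "PBG", pbg)), rb, cfg)
  log <- list()
  for (d in days) {
    recs <- rbind(mk_meas("pt1", "FBG", fbg, day = d),
                  mk_meas("pt1", "PBG", pbg, day = d))
    tasks <- mk_tasks("pt1", max(1, d - 7):d, completed = adherent)
    out <- step(st, recs, tasks, D0 + d, rb, cfg)
    st <- out$state
    log[[length(log) + 1L]] <- out$events
  }
  list(state = st, events = do.call(rbind, log))
}

test_that("a substandard level-2 patient accrues exactly 3 regular follow-ups in 90 days", {
  out <- replay_patient(fbg = 8.0, pbg = 11.5)
  expect_equal(out$state$level, 2L)
  fu <- out$events[out$events$event_type == "followup", ]
  expect_equal(sum(fu$category == "regular"), 3L)
  expect_equal(nrow(fu), 3L)  # no warnings, no compliance events
  expect_equal(fu$date[fu$category == "regular"], D0 + c(30, 60, 90))
})

test_that("an abnormal reading emits a warning and a next-day attention follow-up", {
  prof <- mk_profile()
  st <- enroll(prof, mk_meas("pt1", "FBG", 8.0), rb, cfg)
  out1 <- step(st, mk_meas("pt1", "FBG", 2.9, day = 5), NULL, D0 + 5,
               rb, cfg)
  expect_true(any(out1$events$event_type == "warning" &
                    out1$events$detail == "BG_WARNING"))
  expect_equal(nrow(out1$state$pending_followups), 1L)
  out2 <- step(out1$state, NULL, NULL, D0 + 6, rb, cfg)
  fu <- out2$events[out2$events$event_type == "followup", ]
  expect_equal(fu$category, "abnormal_attention")
  expect_equal(fu$detail, "BG_WARNING")

  # quiet day with nothing due: no events
  out3 <- step(out2$state, NULL, NULL, D0 + 7, rb, cfg)
  expect_equal(nrow(out3$events), 0L)
})

test_that("step is idempotent on a repeated date and rejects going backwards", {
  prof <- mk_profile()
  st <- enroll(prof, mk_meas("pt1", "FBG", 8.0), rb, cfg)
  recs <- mk_meas("pt1", "FBG", 14.5, day = 3)
  out1 <- step(st, recs, NULL, D0 + 3, rb, cfg)
  out2 <- step(out1$state, recs, NULL, D0 + 3, rb, cfg)
  expect_identical(out1$events, out2$events)
  expect_identical(out1$state$pending_followups,
                   out2$state$pending_followups)
  expect_error(step(out1$state, NULL, NULL, D0 + 2, rb, cfg),
               "corrupted replay")
})

test_that("identical replays produce byte-identical event logs", {
  a <- replay_patient(fbg = 9.1, pbg = 12.2)
  b <- replay_patient(fbg = 9.1, pbg = 12.2)
  expect_identical(a$events, b$events)
  expect_identical(a$state$level_history, b$state$level_history)
})

test_that("an intensive-range reading upgrades the level the same day", {
  prof <- mk_profile()
  st <- enroll(prof, rbind(mk_meas("pt1", "FBG", 6.0),
                           mk_meas("pt1", "PBG", 8.0)), rb, cfg)
  expect_equal(st$level, 1L)
  out <- step(st, mk_meas("pt1", "FBG", 12.0, day = 10), NULL, D0 + 10,
              rb, cfg)
  expect_equal(out$state$level, 3L)
  expect_true(any(out$events$event_type == "level_change"))
  expect_true(any(out$events$event_type == "plan_refresh"))
})
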