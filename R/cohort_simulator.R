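#' @title Synthetic cohort simulator
#' @name cohort_simulator
#' @description
#' Generates a synthetic patient cohort emulating the study population
#' (272 patients; 42.6\% with comorbid hypertension; 65.1\% abnormal initial
#' blood glucose; 69.8\% abnormal initial blood pressure among hypertensive
#' patients; 54\% male; age 58.24 +/- 9.81 years) together with
#' intervention-responsive daily glucose/blood-pressure trajectories and
#' task-completion logs, so the whole pathway is testable without any
#' external data. Each patient draws from a pseudo-random stream keyed by
#' (seed, patient_id), so changing the cohort size never perturbs existing
#' patients.
NULL

#' Cohort composition configuration
#'
#' Defaults reproduce the study cohort's marginal composition.
#'
#' @param n_patients Cohort size (default 272).
#' @param p_hypertension Probability of comorbid hypertension (0.426).
#' @param p_abnormal_bg Probability of abnormal initial blood glucose
#'   (0.651).
#' @param p_abnormal_bp_given_htn Probability of abnormal initial blood
#'   pressure among hypertensive patients (0.698).
#' @param p_male Probability of male sex (0.54).
#' @param age_mean,age_sd Adult age distribution (58.24, 9.81 years).
#' @param p_adolescent,p_disability Special-group probabilities (0.026,
#'   0.007).
#' @param seed Mandatory integer seed.
#' @param horizon_days Management horizon (default 90 days = one 3-month
#'   management cycle).
#' @return List of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 272L, p_hypertension = 0.426,
                          p_abnormal_bg = 0.651,
                          p_abnormal_bp_given_htn = 0.698, p_male = 0.54,
                          age_mean = 58.24, age_sd = 9.81,
                          p_adolescent = 0.026, p_disability = 0.007,
                          seed, horizon_days = 90L) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  probs <- c(p_hypertension, p_abnormal_bg, p_abnormal_bp_given_htn,
             p_male, p_adolescent, p_disability)
  stopifnot(all(probs >= 0 & probs <= 1), n_patients >= 1, horizon_days >= 1)
  structure(list(n_patients = as.integer(n_patients),
                 p_hypertension = p_hypertension,
                 p_abnormal_bg = p_abnormal_bg,
                 p_abnormal_bp_given_htn = p_abnormal_bp_given_htn,
                 p_male = p_male, age_mean = age_mean, age_sd = age_sd,
                 p_adolescent = p_adolescent, p_disability = p_disability,
                 seed = as.integer(seed),
                 horizon_days = as.integer(horizon_days)),
            class = "cohort_config")
}

#' Trajectory and adherence model
#'
#' Baseline distributions are normal/abnormal mixtures per the initial
#' assessment; each completed physician follow-up (of any category) lowers
#' the patient's underlying mean trajectory by the per-follow-up effect from
#' the next day onward, floored at physiologically plausible minima.
#' Adherence is patient-specific (Beta-distributed daily task-completion
#' probability) and is boosted by \code{adherence_boost} (capped) after each
#' compliance follow-up.
#'
#' @param effect_per_followup Mean reduction per completed follow-up:
#'   FBG 0.8 and PBG 1.0 mmol/L, SBP 6 and DBP 5 mmHg.
#' @param noise_sd Measurement noise standard deviation per kind.
#' @param adherence_shape1,adherence_shape2 Beta parameters of the daily
#'   task-completion probability (mean 0.7, long low-adherence tail).
#' @param adherence_boost Adherence increase after a compliance follow-up
#'   (+0.2, capped at \code{adherence_cap}).
#' @param p_symptom_day Daily probability of a coded symptom report.
#' @return List of class \code{trajectory_model}.
#' @export
trajectory_model <- function(
    effect_per_followup = c(FBG = 0.8, PBG = 1.0, SBP = 6, DBP = 5),
    noise_sd = c(FBG = 0.6, PBG = 1.1, SBP = 7, DBP = 5, HR = 6),
    adherence_shape1 = 3.5, adherence_shape2 = 1.5,
    adherence_boost = 0.2, adherence_cap = 0.95,
    p_symptom_day = 0.01) {
  stopifnot(all(effect_per_followup >= 0), all(noise_sd > 0),
            adherence_boost >= 0, adherence_cap <= 1)
  structure(list(
    baseline = list(
      fbg_normal = c(mean = 6.1, sd = 0.45, lo = 4.5, hi = 6.9),
      fbg_abnormal = c(mean = 9.6, sd = 1.6, lo = 7.1, hi = 16.0),
      pbg_offset_normal = c(mean = 1.8, sd = 0.5),
      pbg_offset_abnormal = c(mean = 3.2, sd = 0.8),
      sbp_normal = c(mean = 125, sd = 7, lo = 100, hi = 139),
      sbp_abnormal = c(mean = 155, sd = 10, lo = 141, hi = 185),
      dbp_normal = c(mean = 78, sd = 5, lo = 60, hi = 89),
      dbp_abnormal = c(mean = 96, sd = 6, lo = 91, hi = 115),
      hr = c(mean = 76, sd = 7), weight = c(mean = 70, sd = 12,
                                            lo = 45, hi = 110)
    ),
    effect_per_followup = effect_per_followup,
    noise_sd = noise_sd,
    floor = c(FBG = 4.8, PBG = 5.8, SBP = 108, DBP = 68),
    adherence_shape1 = adherence_shape1,
    adherence_shape2 = adherence_shape2,
    adherence_boost = adherence_boost, adherence_cap = adherence_cap,
    p_symptom_day = p_symptom_day,
    severity_probs = c(0.6, 0.3, 0.1)
  ), class = "trajectory_model")
}

# deterministic per-patient seed keyed by (seed, patient_id): cohort size
# changes never perturb an existing patient's stream
patient_seed <- function(seed, patient_id) {
  m <- 2147480009  # prime below 2^31
  h <- 0
  for (ch in utf8ToInt(patient_id)) h <- (h * 31 + ch) %% m
  as.integer((h + (as.numeric(seed) %% m) * 48271) %% m)
}

rnorm_clip <- function(n, par) {
  x <- stats::rnorm(n, par[["mean"]], par[["sd"]])
  if (!is.na(par["lo"])) x <- pmax(par[["lo"]], pmin(par[["hi"]], x))
  x
}

ENROLL_DATE <- as.Date("2020-01-01")

# draws everything a patient needs, in a fixed order, from the patient's
# own stream: profile attributes, baselines, and day-indexed noise matrices
setup_patient <- function(patient_id, config, model) {
  set.seed(patient_seed(config$seed, patient_id))
  H <- config$horizon_days
  adolescent <- stats::runif(1) < config$p_adolescent
  age <- if (adolescent) sample(13:17, 1) else
    as.integer(round(pmin(85, pmax(19, stats::rnorm(1, config$age_mean,
                                                    config$age_sd)))))
  p <- list(
    patient_id = patient_id,
    sex = if (stats::runif(1) < config$p_male) "male" else "female",
    age = age,
    adolescent = adolescent,
    disability = stats::runif(1) < config$p_disability,
    htn = stats::runif(1) < config$p_hypertension,
    abn_bg = stats::runif(1) < config$p_abnormal_bg,
    bmi = round(pmax(17, pmin(40, stats::rnorm(1, 25.5, 3.5))), 1),
    smoker = stats::runif(1) < 0.25,
    p_adh = stats::rbeta(1, model$adherence_shape1, model$adherence_shape2)
  )
  p$abn_bp <- p$htn && stats::runif(1) < config$p_abnormal_bp_given_htn
  b <- model$baseline
  p$fbg0 <- rnorm_clip(1, if (p$abn_bg) b$fbg_abnormal else b$fbg_normal)
  off <- if (p$abn_bg) b$pbg_offset_abnormal else b$pbg_offset_normal
  p$pbg0 <- p$fbg0 + pmax(0.5, stats::rnorm(1, off[["mean"]], off[["sd"]]))
  if (p$htn) {
    p$sbp0 <- rnorm_clip(1, if (p$abn_bp) b$sbp_abnormal else b$sbp_normal)
    p$dbp0 <- rnorm_clip(1, if (p$abn_bp) b$dbp_abnormal else b$dbp_normal)
  }
  p$hr0 <- stats::rnorm(1, b$hr[["mean"]], b$hr[["sd"]])
  p$wt0 <- rnorm_clip(1, b$weight)
  # day-indexed noise: Z columns FBG/PBG/SBP/DBP/HR, U columns
  # bg-adherence / bp-adherence / med-adherence / symptom / severity
  p$Z <- matrix(stats::rnorm(H * 5), nrow = H,
                dimnames = list(NULL, c("FBG", "PBG", "SBP", "DBP", "HR")))
  p$U <- matrix(stats::runif(H * 5), nrow = H,
                dimnames = list(NULL,
                                c("bg", "bp", "med", "sym", "sev")))
  p$profile <- patient_profile(
    patient_id, p$sex, p$age,
    diseases = c("diabetes", if (p$htn) "hypertension"),
    enrollment_date = ENROLL_DATE,
    special_group = c(if (p$adolescent) "adolescent",
                      if (p$disability) "disability"),
    bmi = p$bmi, smoker = p$smoker)
  p
}

initial_level <- function(p, config) {
  tg <- config$targets
  if (p$fbg0 > tg$intensive_fbg) 3L
  else if (p$fbg0 <= tg$fbg && p$pbg0 <= tg$pbg) 1L
  else 2L
}

severity_from_u <- function(u, probs) {
  findInterval(u, cumsum(probs)) + 1L
}

#' Simulate a synthetic cohort (open loop)
#'
#' Generates profiles, a 90-day measurement stream and task-completion log
#' for every patient, with a simplified internal intervention process
#' mirroring the pathway defaults: the initial management level follows the
#' glycemic thresholds, regular follow-ups fall at the level's interval,
#' an abnormal-range reading draws a physician follow-up the next day
#' (debounced), and a weekly compliance check below the low-compliance
#' cutoff draws a motivational follow-up that boosts adherence. Every
#' completed follow-up lowers the underlying trajectories by the model's
#' per-follow-up effect from the next day onward. Fully reproducible given
#' the seed.
#'
#' @param config A \code{cohort_config}.
#' @param model A \code{trajectory_model}.
#' @param pathway_config Pathway configuration supplying thresholds,
#'   monitoring frequencies and follow-up intervals.
#' @return List of class \code{sim_cohort}: \code{profiles} (list),
#'   \code{patients} (baseline data.frame), \code{measurements},
#'   \code{tasks}, \code{followups} (simulator ground-truth intervention
#'   log), plus the configs.
#' @export
simulate_cohort <- function(config, model = trajectory_model(),
                            pathway_config = default_config()) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- sprintf("P%04d", seq_len(config$n_patients))
  H <- config$horizon_days
  th <- pathway_config$thresholds
  cw <- pathway_config$compliance
  eff <- model$effect_per_followup
  ns <- model$noise_sd
  fl <- model$floor

  profiles <- vector("list", length(ids))
  pat_rows <- vector("list", length(ids))
  meas <- vector("list", length(ids))
  task <- vector("list", length(ids))
  fups <- vector("list", length(ids))

  for (i in seq_along(ids)) {
    p <- setup_patient(ids[i], config, model)
    profiles[[i]] <- p$profile
    lvl <- initial_level(p, pathway_config)
    freq <- pathway_config$monitoring$bg_days_per_week[[as.character(lvl)]]
    iv <- pathway_config$followup_interval_days[[as.character(lvl)]]
    regular_days <- seq_len(floor(H / iv)) * iv
    p_adh <- p$p_adh

    n_fu <- 0L           # completed follow-ups so far (drives effects)
    pending_abn <- NA_integer_
    m_day <- integer(); m_kind <- character(); m_val <- numeric()
    t_day <- integer(); t_task <- character(); t_done <- logical()
    f_day <- integer(); f_cat <- character()
    sched_hist <- logical(0); done_hist <- logical(0)  # per-task, in order
    sched_day <- integer(0)

    add_meas <- function(day, kind, val) {
      m_day[length(m_day) + 1L] <<- day
      m_kind[length(m_kind) + 1L] <<- kind
      m_val[length(m_val) + 1L] <<- val
    }
    add_task <- function(day, tk, done) {
      t_day[length(t_day) + 1L] <<- day
      t_task[length(t_task) + 1L] <<- tk
      t_done[length(t_done) + 1L] <<- done
      sched_day[length(sched_day) + 1L] <<- day
      done_hist[length(done_hist) + 1L] <<- done
    }

    for (day in seq_len(H)) {
      warned <- FALSE
      # pending abnormal-attention follow-up conducted today
      if (!is.na(pending_abn) && pending_abn <= day) {
        f_day[length(f_day) + 1L] <- day
        f_cat[length(f_cat) + 1L] <- "abnormal_attention"
        n_fu <- n_fu + 1L
        pending_abn <- NA_integer_
      }
      # daily medication self-task
      med_done <- p$U[day, "med"] < p_adh
      add_task(day, "medication_guidance", med_done)
      # blood-glucose profile on plan days
      if (((day - 1L) %% 7L) < freq) {
        done <- p$U[day, "bg"] < p_adh
        add_task(day, "self_monitoring", done)
        if (done) {
          fbg <- max(fl[["FBG"]], p$fbg0 - eff[["FBG"]] * n_fu) +
            p$Z[day, "FBG"] * ns[["FBG"]]
          pbg <- max(fl[["PBG"]], p$pbg0 - eff[["PBG"]] * n_fu) +
            p$Z[day, "PBG"] * ns[["PBG"]]
          fbg <- max(0.6, fbg); pbg <- max(0.8, pbg)
          add_meas(day, "FBG", fbg)
          add_meas(day, "PBG", pbg)
          add_meas(day, "HR", p$hr0 + p$Z[day, "HR"] * ns[["HR"]])
          if (fbg < th$bg_low || fbg >= th$fbg_high || pbg < th$bg_low ||
              pbg >= th$bg_high) warned <- TRUE
        }
      }
      # daily home blood pressure for comorbid hypertension
      if (p$htn && pathway_config$monitoring$bp_daily_if_hypertension) {
        done <- p$U[day, "bp"] < p_adh
        add_task(day, "self_monitoring", done)
        if (done) {
          sbp <- max(fl[["SBP"]], p$sbp0 - eff[["SBP"]] * n_fu) +
            p$Z[day, "SBP"] * ns[["SBP"]]
          dbp <- max(fl[["DBP"]], p$dbp0 - eff[["DBP"]] * n_fu) +
            p$Z[day, "DBP"] * ns[["DBP"]]
          add_meas(day, "SBP", sbp)
          add_meas(day, "DBP", dbp)
          if (sbp >= th$sbp_high || sbp < th$sbp_low || dbp >= th$dbp_high)
            warned <- TRUE
        }
      }
      # occasional coded symptom report
      if (p$U[day, "sym"] < model$p_symptom_day) {
        sev <- severity_from_u(p$U[day, "sev"], model$severity_probs)
        add_meas(day, "SYMPTOM", sev)
        if (sev >= th$symptom_severity) warned <- TRUE
      }
      if (warned && is.na(pending_abn)) pending_abn <- day + 1L
      # weekly compliance check
      if (day %% cw$window_days == 0L) {
        win <- sched_day > day - cw$window_days & sched_day <= day
        rate <- if (!any(win)) 1 else sum(done_hist[win]) / sum(win)
        if (rate < cw$low_rate) {
          f_day[length(f_day) + 1L] <- day
          f_cat[length(f_cat) + 1L] <- "compliance"
          n_fu <- n_fu + 1L
          p_adh <- min(model$adherence_cap, p_adh + model$adherence_boost)
        }
      }
      # regular follow-up
      if (day %in% regular_days) {
        f_day[length(f_day) + 1L] <- day
        f_cat[length(f_cat) + 1L] <- "regular"
        n_fu <- n_fu + 1L
      }
    }

    pat_rows[[i]] <- data.frame(
      patient_id = ids[i], sex = p$sex, age = p$age, hypertension = p$htn,
      abnormal_bg = p$abn_bg, abnormal_bp = isTRUE(p$abn_bp),
      adolescent = p$adolescent, disability = p$disability,
      fbg0 = p$fbg0, pbg0 = p$pbg0,
      sbp0 = if (p$htn) p$sbp0 else NA_real_,
      dbp0 = if (p$htn) p$dbp0 else NA_real_,
      p_adherence = p$p_adh, initial_level = lvl,
      n_followups = n_fu, stringsAsFactors = FALSE)
    if (length(m_day) > 0) {
      meas[[i]] <- data.frame(patient_id = ids[i], kind = m_kind,
                              value = m_val, day = m_day,
                              stringsAsFactors = FALSE)
    }
    if (length(t_day) > 0) {
      task[[i]] <- data.frame(patient_id = ids[i], task = t_task,
                              day = t_day, completed = t_done,
                              stringsAsFactors = FALSE)
    }
    if (length(f_day) > 0) {
      fups[[i]] <- data.frame(patient_id = ids[i], day = f_day,
                              category = f_cat, stringsAsFactors = FALSE)
    }
  }

  measurements <- do.call(rbind, meas[!vapply(meas, is.null, TRUE)])
  tasks <- do.call(rbind, task[!vapply(task, is.null, TRUE)])
  followups <- do.call(rbind, fups[!vapply(fups, is.null, TRUE)])
  if (is.null(followups)) {
    followups <- data.frame(patient_id = character(), day = integer(),
                            category = character(), stringsAsFactors = FALSE)
  }
  measurements$timestamp <- as.POSIXct(ENROLL_DATE + measurements$day,
                                       tz = "UTC")
  tasks$scheduled_date <- ENROLL_DATE + tasks$day
  tasks$completed_date <- as.Date(ifelse(tasks$completed,
                                         tasks$scheduled_date, NA),
                                  origin = "1970-01-01")
  followups$date <- ENROLL_DATE + followups$day

  structure(list(profiles = profiles,
                 patients = do.call(rbind, pat_rows),
                 measurements = measurements, tasks = tasks,
                 followups = followups, config = config, model = model,
                 pathway_config = pathway_config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", nrow(x$patients), "patients,",
      nrow(x$measurements), "measurements over",
      x$config$horizon_days, "days (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Replay a cohort through the closed-loop engine
#'
#' Co-simulates every patient day by day through \code{\link{step}}: daily
#' records are generated from the patient's current plan frequencies and
#' adherence, fed to the engine, and each follow-up the engine emits is
#' completed by the physician (modelled as an immediate event consumer),
#' lowering the patient's underlying trajectory per the model's
#' per-follow-up effect and boosting adherence after compliance follow-ups.
#'
#' @param cohort A \code{sim_cohort} (profiles and baseline draws are
#'   reused; the open-loop records are not).
#' @param rules A \code{rulebase}.
#' @param config Pathway configuration.
#' @return List: \code{events} (full event log), \code{states} (final
#'   pathway states), \code{measurements}, \code{tasks}.
#' @export
run_closed_loop <- function(cohort, rules = default_rulebase(),
                            config = default_config()) {
  stopifnot(inherits(cohort, "sim_cohort"))
  model <- cohort$model
  H <- cohort$config$horizon_days
  eff <- model$effect_per_followup
  ns <- model$noise_sd
  fl <- model$floor
  th <- config$thresholds

  all_events <- list()
  all_meas <- list()
  all_tasks <- list()
  states <- list()

  for (i in seq_along(cohort$profiles)) {
    prof <- cohort$profiles[[i]]
    pid <- prof$patient_id
    p <- setup_patient(pid, cohort$config, model)
    init <- data.frame(
      patient_id = pid,
      kind = c("FBG", "PBG", if (p$htn) c("SBP", "DBP")),
      value = c(p$fbg0, p$pbg0, if (p$htn) c(p$sbp0, p$dbp0)),
      timestamp = as.POSIXct(ENROLL_DATE, tz = "UTC"),
      stringsAsFactors = FALSE)
    state <- enroll(prof, init, rules, config)
    p_adh <- p$p_adh
    n_fu <- 0L
    t_day <- integer(); t_task <- character(); t_done <- logical()
    ev <- list()
    m <- list()

    for (day in seq_len(H)) {
      date <- ENROLL_DATE + day
      freq <- config$monitoring$bg_days_per_week[[as.character(state$level)]]
      kinds <- character(); vals <- numeric()
      done_today <- logical(); task_today <- character()

      done <- p$U[day, "med"] < p_adh
      task_today <- c(task_today, "medication_guidance")
      done_today <- c(done_today, done)
      if (((day - 1L) %% 7L) < freq) {
        done <- p$U[day, "bg"] < p_adh
        task_today <- c(task_today, "self_monitoring")
        done_today <- c(done_today, done)
        if (done) {
          fbg <- max(0.6, max(fl[["FBG"]], p$fbg0 - eff[["FBG"]] * n_fu) +
                       p$Z[day, "FBG"] * ns[["FBG"]])
          pbg <- max(0.8, max(fl[["PBG"]], p$pbg0 - eff[["PBG"]] * n_fu) +
                       p$Z[day, "PBG"] * ns[["PBG"]])
          kinds <- c(kinds, "FBG", "PBG", "HR")
          vals <- c(vals, fbg, pbg, p$hr0 + p$Z[day, "HR"] * ns[["HR"]])
        }
      }
      if (p$htn && config$monitoring$bp_daily_if_hypertension) {
        done <- p$U[day, "bp"] < p_adh
        task_today <- c(task_today, "self_monitoring")
        done_today <- c(done_today, done)
        if (done) {
          kinds <- c(kinds, "SBP", "DBP")
          vals <- c(vals,
                    max(fl[["SBP"]], p$sbp0 - eff[["SBP"]] * n_fu) +
                      p$Z[day, "SBP"] * ns[["SBP"]],
                    max(fl[["DBP"]], p$dbp0 - eff[["DBP"]] * n_fu) +
                      p$Z[day, "DBP"] * ns[["DBP"]])
        }
      }
      if (p$U[day, "sym"] < model$p_symptom_day) {
        kinds <- c(kinds, "SYMPTOM")
        vals <- c(vals, severity_from_u(p$U[day, "sev"],
                                        model$severity_probs))
      }

      t_day <- c(t_day, rep(day, length(task_today)))
      t_task <- c(t_task, task_today)
      t_done <- c(t_done, done_today)

      day_records <- if (length(kinds) > 0) data.frame(
        patient_id = pid, kind = kinds, value = vals,
        timestamp = as.POSIXct(date, tz = "UTC"),
        stringsAsFactors = FALSE) else NULL
      keep <- t_day > day - 8L
      day_tasks <- data.frame(
        patient_id = pid, task = t_task[keep],
        scheduled_date = ENROLL_DATE + t_day[keep],
        completed = t_done[keep],
        completed_date = as.Date(ifelse(t_done[keep],
                                        ENROLL_DATE + t_day[keep], NA),
                                 origin = "1970-01-01"),
        stringsAsFactors = FALSE)

      out <- step(state, day_records, day_tasks, date, rules, config)
      state <- out$state
      if (nrow(out$events) > 0) {
        ev[[length(ev) + 1L]] <- out$events
        fu <- out$events[out$events$event_type == "followup", , drop = FALSE]
        if (nrow(fu) > 0) {
          n_fu <- n_fu + nrow(fu)  # physician completes immediately
          if (any(fu$category == "compliance")) {
            p_adh <- min(model$adherence_cap,
                         p_adh + model$adherence_boost)
          }
        }
      }
      if (!is.null(day_records)) m[[length(m) + 1L]] <- day_records
    }
    states[[pid]] <- state
    if (length(ev) > 0) all_events[[pid]] <- do.call(rbind, ev)
    if (length(m) > 0) all_meas[[pid]] <- do.call(rbind, m)
    all_tasks[[pid]] <- data.frame(
      patient_id = pid, task = t_task, scheduled_date = ENROLL_DATE + t_day,
      completed = t_done,
      completed_date = as.Date(ifelse(t_done, ENROLL_DATE + t_day, NA),
                               origin = "1970-01-01"),
      stringsAsFactors = FALSE)
  }

  events <- if (length(all_events) > 0) do.call(rbind, all_events) else
    empty_events()
  rownames(events) <- NULL
  list(events = events, states = states,
       measurements = do.call(rbind, all_meas),
       tasks = do.call(rbind, all_tasks))
}
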