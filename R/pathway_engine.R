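#' @title Closed-loop pathway state machine
#' @name pathway_engine
#' @description
#' Enrollment with risk assessment and hierarchical level assignment,
#' periodic re-evaluation with level transitions (immediate upgrade,
#' hysteretic downgrade), regular follow-up scheduling by level, and the
#' daily step function that drives warning detection, compliance checks and
#' due follow-ups, emitting an auditable event log.
NULL

LEVEL_1_ROUTINE <- 1L
LEVEL_2_ROUTINE <- 2L
LEVEL_3_INTENSIVE <- 3L

#' Management level labels
#' @return Named integer vector of the three hierarchical management levels
#'   (routine level 1 < routine level 2 < intensive level 3).
#' @export
management_levels <- function() {
  c(LEVEL_1_ROUTINE = 1L, LEVEL_2_ROUTINE = 2L, LEVEL_3_INTENSIVE = 3L)
}

interval_for_level <- function(level, config) {
  as.integer(config$followup_interval_days[[as.character(level)]])
}

#' Assign a hierarchical management level from a fact base
#'
#' Runs the rule base on the facts and reads the derived management level:
#' intensive level 3 iff the fasting glucose strictly exceeds the intensive
#' bound (default 11.1 mmol/L), routine level 1 iff all available glucose
#' readings are within control targets, otherwise routine level 2. With no
#' glucose facts at all the patient defaults to level 2 and the result
#' carries an \code{insufficient_data} attribute.
#'
#' @param facts A \code{factbase}.
#' @param rules A \code{rulebase}.
#' @param config Pathway configuration.
#' @return Integer level 1, 2 or 3 (attribute \code{insufficient_data} when
#'   no glucose data informed the decision).
#' @export
assess_level <- function(facts, rules = default_rulebase(),
                         config = default_config()) {
  fl <- if (inherits(facts, "factbase")) facts$facts else facts
  has_bg <- any(c("latest_FBG", "latest_PBG") %in% names(fl))
  if (!has_bg) {
    lvl <- LEVEL_2_ROUTINE
    attr(lvl, "insufficient_data") <- TRUE
    message("no blood glucose facts; defaulting to routine level 2")
    return(lvl)
  }
  res <- infer(facts, rules)
  lvl <- res$single$management_level
  if (is.null(lvl)) {
    lvl <- LEVEL_2_ROUTINE
    attr(lvl, "insufficient_data") <- TRUE
    return(lvl)
  }
  as.integer(lvl)
}

#' Enroll a patient into the management pathway
#'
#' On diagnosis a patient enters the pathway: a cardiovascular risk
#' assessment is run over the rule base, the initial hierarchical level is
#' assigned from the baseline readings, and the first regular follow-up is
#' scheduled at \code{cycle_start + interval(level)}.
#'
#' @param profile A \code{patient_profile} (must include diabetes).
#' @param initial_records Baseline measurement data.frame (timestamps on or
#'   after enrollment).
#' @param rules A \code{rulebase}.
#' @param config Pathway configuration.
#' @return An object of class \code{pathway_state}.
#' @export
enroll <- function(profile, initial_records = NULL,
                   rules = default_rulebase(), config = default_config()) {
  if (!"diabetes" %in% profile$diseases) {
    stop("pathway admits only patients with diabetes", call. = FALSE)
  }
  as_of <- profile$enrollment_date
  if (!is.null(initial_records) && nrow(initial_records) > 0) {
    for (i in seq_len(nrow(initial_records))) {
      validate_record(initial_records[i, ], profile$enrollment_date)
    }
    as_of <- max(c(as_of, as.Date(as_timestamp(initial_records$timestamp))))
  }
  fb <- build_factbase(profile, initial_records, NULL, as_of, config)
  res <- infer(fb, rules)
  level <- assess_level(fb, rules, config)
  state <- structure(list(
    patient_id = profile$patient_id,
    profile = profile,
    level = as.integer(level),
    level_history = data.frame(date = as_of, level = as.integer(level)),
    risk_level = res$single$risk_level %||% "low",
    risk_factors = unlist(res$multi$risk_factor) %||% character(),
    cycle_start = profile$enrollment_date,
    next_regular_followup = profile$enrollment_date +
      interval_for_level(level, config),
    last_eval_date = as_of,
    downgrade_streak = 0L,
    open_warnings = empty_warnings(),
    pending_followups = empty_events(),
    compliance_low = FALSE,
    last_compliance_followup = as.Date(NA),
    recent_records = if (is.null(initial_records)) NULL else initial_records,
    last_step_date = as.Date(NA),
    last_events = empty_events()
  ), class = "pathway_state")
  state
}

#' @export
print.pathway_state <- function(x, ...) {
  cat("<pathway_state>", x$patient_id, "- level", x$level,
      "| next regular follow-up", format(x$next_regular_followup),
      "| open warnings:", nrow(x$open_warnings), "\n")
  invisible(x)
}

#' Periodic re-evaluation of a patient's management level
#'
#' Rebuilds the fact base as of \code{date} and re-assesses the level on
#' trailing 30-day mean readings (means stand in for the latest readings
#' during re-evaluation, damping single-reading noise). An upgrade to a more
#' intensive level takes effect immediately; a downgrade requires two
#' consecutive in-target evaluations (hysteresis against level oscillation).
#' With no recent glucose data the level is left unchanged and a flag is
#' logged.
#'
#' @param state A \code{pathway_state}.
#' @param records Measurement history (trailing window suffices).
#' @param date Evaluation date.
#' @param rules A \code{rulebase}.
#' @param config Pathway configuration.
#' @return The updated \code{pathway_state}.
#' @export
reevaluate <- function(state, records, date, rules = default_rulebase(),
                       config = default_config()) {
  date <- as.Date(date)
  fb <- build_factbase(state$profile, records, NULL, date, config)
  # assessment facts: trailing 30-day means replace latest readings
  for (k in c("FBG", "PBG", "SBP", "DBP")) {
    mk <- paste0("mean_", k, "_30d")
    if (!is.null(fb$facts[[mk]])) fb$facts[[paste0("latest_", k)]] <-
        fb$facts[[mk]]
  }
  has_bg <- any(c("latest_FBG", "latest_PBG") %in% names(fb$facts))
  state$last_eval_date <- date
  if (!has_bg) {
    message("re-evaluation without recent glucose data for ",
            state$patient_id, "; level unchanged")
    return(state)
  }
  candidate <- as.integer(assess_level(fb, rules, config))
  if (candidate > state$level) {
    state$level <- candidate
    state$level_history <- rbind(state$level_history,
                                 data.frame(date = date, level = candidate))
    state$downgrade_streak <- 0L
  } else if (candidate < state$level) {
    state$downgrade_streak <- state$downgrade_streak + 1L
    if (state$downgrade_streak >= 2L) {
      state$level <- candidate
      state$level_history <- rbind(state$level_history,
                                   data.frame(date = date, level = candidate))
      state$downgrade_streak <- 0L
    }
  } else {
    state$downgrade_streak <- 0L
  }
  state
}

#' Regular follow-up dates for a level over a horizon
#'
#' Dates fall at \code{cycle_start + k * interval(level)} for k >= 1 within
#' the horizon. Default intervals: level 1 every 90 days, levels 2 and 3
#' monthly (every 30 days) — so a substandard (level 2) patient accrues
#' exactly 3 regular follow-ups in a 90-day management cycle.
#'
#' @param level Management level (1, 2 or 3).
#' @param cycle_start Cycle start date.
#' @param horizon_days Horizon length in days (>= 0).
#' @param config Pathway configuration.
#' @return Vector of Dates (possibly empty).
#' @export
schedule_regular_followups <- function(level, cycle_start, horizon_days,
                                       config = default_config()) {
  stopifnot(horizon_days >= 0)
  cycle_start <- as.Date(cycle_start)
  iv <- interval_for_level(level, config)
  k <- seq_len(floor(horizon_days / iv))
  cycle_start + k * iv
}

#' Advance a patient one day through the closed loop
#'
#' The daily driver: detects warnings in the day's records (scheduling an
#' abnormal-attention follow-up for the next day), applies an immediate
#' level upgrade when a fasting reading exceeds the intensive bound, checks
#' compliance (debounced compliance follow-up), emits due abnormal-attention
#' and regular follow-ups, and runs the periodic re-evaluation (emitting
#' level-change and plan-refresh events on a transition). A repeated call
#' with the same date is idempotent; a date moving backwards signals a
#' corrupted replay and errors.
#'
#' @param state A \code{pathway_state}.
#' @param day_records The day's measurement records (may be empty/NULL).
#' @param day_tasks Task records up to \code{date} (the trailing compliance
#'   window is extracted internally; may be NULL).
#' @param date Current date (must advance strictly between distinct calls).
#' @param rules A \code{rulebase}.
#' @param config Pathway configuration.
#' @return List with elements \code{state} (updated) and \code{events}
#'   (data.frame: date, patient_id, event_type, category, detail).
#' @export
step <- function(state, day_records = NULL, day_tasks = NULL, date,
                 rules = default_rulebase(), config = default_config()) {
  date <- as.Date(date)
  if (!is.na(state$last_step_date)) {
    if (date < state$last_step_date) {
      stop("step date moved backwards (", format(date), " < ",
           format(state$last_step_date), "): corrupted replay",
           call. = FALSE)
    }
    if (date == state$last_step_date) {
      return(list(state = state, events = state$last_events))
    }
  }
  events <- list()
  emit <- function(event_type, category = NA_character_,
                   detail = NA_character_, when = date) {
    events[[length(events) + 1L]] <<- data.frame(
      date = when, patient_id = state$patient_id, event_type = event_type,
      category = category, detail = detail, stringsAsFactors = FALSE)
  }

  # accumulate trailing records for re-evaluation windows
  if (!is.null(day_records) && nrow(day_records) > 0) {
    state$recent_records <- rbind(state$recent_records, day_records)
  }
  if (!is.null(state$recent_records) && nrow(state$recent_records) > 0) {
    keep <- as.Date(as_timestamp(state$recent_records$timestamp)) > date - 35
    state$recent_records <- state$recent_records[keep, , drop = FALSE]
  }

  # 1. abnormal-attention warnings on today's records
  warnings_today <- detect_warnings(day_records, config)
  if (nrow(warnings_today) > 0) {
    for (i in seq_len(nrow(warnings_today))) {
      emit("warning", detail = warnings_today$type[i])
    }
    fu <- trigger_variation_followups(warnings_today, NULL, state, config)
    state$pending_followups <- rbind(state$pending_followups, fu)
    state$open_warnings <- rbind(state$open_warnings, warnings_today)
  }

  # 2. immediate upgrade on an intensive-range fasting reading
  if (!is.null(day_records) && nrow(day_records) > 0) {
    fbg_today <- day_records$value[day_records$kind == "FBG"]
    if (length(fbg_today) > 0 &&
        max(fbg_today) > config$targets$intensive_fbg &&
        state$level < LEVEL_3_INTENSIVE) {
      state$level <- LEVEL_3_INTENSIVE
      state$level_history <- rbind(
        state$level_history,
        data.frame(date = date, level = LEVEL_3_INTENSIVE))
      state$downgrade_streak <- 0L
      emit("level_change", detail = "upgrade to intensive level 3")
      emit("plan_refresh", detail = "level 3")
      state$next_regular_followup <-
        date + interval_for_level(LEVEL_3_INTENSIVE, config)
    }
  }

  # 3. compliance check (debounced to once per window)
  if (!is.null(day_tasks) && nrow(day_tasks) > 0) {
    cs <- compliance_rate(day_tasks, date,
                          window_days = config$compliance$window_days,
                          low_rate = config$compliance$low_rate)
    state$compliance_low <- cs$low
    fu <- trigger_variation_followups(empty_warnings(), cs, state, config)
    if (nrow(fu) > 0) {
      state$last_compliance_followup <- date
      for (i in seq_len(nrow(fu))) {
        emit("followup", category = "compliance", detail = fu$detail[i])
      }
    }
  }

  # 4. due abnormal-attention follow-ups (scheduled for today or earlier)
  if (nrow(state$pending_followups) > 0) {
    due <- state$pending_followups$date <= date
    if (any(due)) {
      for (i in which(due)) {
        emit("followup", category = "abnormal_attention",
             detail = state$pending_followups$detail[i])
      }
      resolved_types <- state$pending_followups$detail[due]
      state$open_warnings$resolved[
        state$open_warnings$type %in% resolved_types] <- TRUE
      state$pending_followups <-
        state$pending_followups[!due, , drop = FALSE]
    }
  }

  # 5. due regular follow-ups
  while (state$next_regular_followup <= date) {
    emit("followup", category = "regular",
         detail = sprintf("level %d scheduled %s", state$level,
                          format(state$next_regular_followup)))
    state$next_regular_followup <- state$next_regular_followup +
      interval_for_level(state$level, config)
  }

  # 6. periodic re-evaluation
  if (as.integer(date - state$last_eval_date) >=
      config$reeval_interval_days) {
    old_level <- state$level
    state <- reevaluate(state, state$recent_records, date, rules, config)
    if (state$level != old_level) {
      emit("level_change",
           detail = sprintf("level %d -> %d", old_level, state$level))
      emit("plan_refresh", detail = sprintf("level %d", state$level))
      state$next_regular_followup <-
        date + interval_for_level(state$level, config)
    }
  }

  ev <- if (length(events) == 0) empty_events() else do.call(rbind, events)
  rownames(ev) <- NULL
  state$last_step_date <- date
  state$last_events <- ev
  list(state = state, events = ev)
}
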