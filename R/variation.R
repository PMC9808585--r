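#' @title Pathway variation: abnormal-attention warnings and compliance
#' @name variation
#' @description
#' The pathway-variation task set: detection of abnormal self-monitoring
#' data (blood glucose, blood pressure, disorder/symptom, heart rate
#' warnings) and of low task compliance, each of which triggers additional
#' physician follow-up beyond the regular schedule.
NULL

WARNING_TYPES <- c("BG_WARNING", "BP_WARNING", "DISORDER_WARNING",
                   "HR_WARNING")

FOLLOWUP_CATEGORIES <- c("regular", "abnormal_attention", "compliance")

empty_warnings <- function() {
  data.frame(patient_id = character(), type = character(),
             kind = character(), value = numeric(),
             date = as.Date(character()), resolved = logical(),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(date = as.Date(character()), patient_id = character(),
             event_type = character(), category = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' Detect abnormal-attention warnings in a day's records
#'
#' Classifies a day's measurements against the configured alert bounds:
#' blood glucose below \code{bg_low} or at/above \code{bg_high} (fasting
#' additionally at/above \code{fbg_high}); systolic pressure at/above
#' \code{sbp_high} or below \code{sbp_low}, diastolic at/above
#' \code{dbp_high}; heart rate below \code{hr_low} or above \code{hr_high};
#' any symptom record with coded severity at/above the configured grade.
#' At most one warning per (patient, type, day) is emitted (debounce).
#'
#' @param day_records Measurement data.frame for one or more patients.
#' @param config Pathway configuration.
#' @return Warning data.frame: patient_id, type, kind, value, date,
#'   resolved (FALSE).
#' @export
detect_warnings <- function(day_records, config = default_config()) {
  if (is.null(day_records) || nrow(day_records) == 0) return(empty_warnings())
  th <- config$thresholds
  r <- day_records
  r$timestamp <- as_timestamp(r$timestamp)
  type <- rep(NA_character_, nrow(r))

  bg <- r$kind %in% c("FBG", "PBG")
  type[bg & (r$value < th$bg_low | r$value >= th$bg_high)] <- "BG_WARNING"
  type[r$kind == "FBG" & r$value >= th$fbg_high] <- "BG_WARNING"
  type[r$kind == "SBP" & (r$value >= th$sbp_high | r$value < th$sbp_low)] <-
    "BP_WARNING"
  type[r$kind == "DBP" & r$value >= th$dbp_high] <- "BP_WARNING"
  type[r$kind == "HR" & (r$value < th$hr_low | r$value > th$hr_high)] <-
    "HR_WARNING"
  type[r$kind == "SYMPTOM" & r$value >= th$symptom_severity] <-
    "DISORDER_WARNING"

  hit <- !is.na(type)
  if (!any(hit)) return(empty_warnings())
  w <- data.frame(patient_id = r$patient_id[hit], type = type[hit],
                  kind = r$kind[hit], value = r$value[hit],
                  date = as.Date(r$timestamp[hit]), resolved = FALSE,
                  stringsAsFactors = FALSE)
  # debounce: one warning per (patient, type, day)
  w <- w[!duplicated(w[, c("patient_id", "type", "date")]), , drop = FALSE]
  rownames(w) <- NULL
  w
}

#' Task compliance over a trailing window
#'
#' The compliance rate is completed / scheduled over tasks scheduled in
#' \code{(as_of - window_days, as_of]}; a window with nothing scheduled is
#' vacuously compliant (rate 1). Compliance is low when the rate falls below
#' the configured cutoff.
#'
#' @param tasks Task record data.frame.
#' @param as_of Evaluation date.
#' @param window_days Trailing window length in days (>= 1).
#' @param low_rate Low-compliance cutoff on the rate.
#' @return List of class \code{compliance_status}: patient_id, as_of,
#'   window_days, scheduled, completed, rate, low.
#' @export
compliance_rate <- function(tasks, as_of, window_days = 7L,
                            low_rate = 0.5) {
  stopifnot(window_days >= 1)
  as_of <- as.Date(as_of)
  pid <- if (!is.null(tasks) && nrow(tasks) > 0) tasks$patient_id[1] else
    NA_character_
  if (is.null(tasks) || nrow(tasks) == 0) {
    sched <- 0L; comp <- 0L
  } else {
    in_win <- tasks$scheduled_date > as_of - window_days &
      tasks$scheduled_date <= as_of
    sched <- sum(in_win)
    comp <- sum(in_win & tasks$completed)
  }
  rate <- if (sched == 0) 1.0 else comp / sched
  structure(list(patient_id = pid, as_of = as_of,
                 window_days = as.integer(window_days),
                 scheduled = sched, completed = comp, rate = rate,
                 low = rate < low_rate),
            class = "compliance_status")
}

#' Variation-triggered follow-up events
#'
#' Maps warnings and compliance status to physician follow-up events: one
#' abnormal-attention follow-up on the day after each unresolved warning,
#' and at most one compliance follow-up per compliance window (debounced
#' against the state's last compliance follow-up date). Every emitted event
#' carries exactly one of the three follow-up categories (regular /
#' abnormal_attention / compliance).
#'
#' @param warnings Warning data.frame (see \code{\link{detect_warnings}}).
#' @param compliance A \code{compliance_status} (or NULL).
#' @param state A \code{pathway_state} (used for the compliance debounce;
#'   may be NULL for stateless use).
#' @param config Pathway configuration.
#' @return Follow-up event data.frame (date, patient_id, event_type =
#'   "followup", category, detail).
#' @export
trigger_variation_followups <- function(warnings, compliance = NULL,
                                        state = NULL,
                                        config = default_config()) {
  ev <- list()
  if (!is.null(warnings) && nrow(warnings) > 0) {
    open <- warnings[!warnings$resolved, , drop = FALSE]
    if (nrow(open) > 0) {
      ev[[length(ev) + 1L]] <- data.frame(
        date = open$date + 1L, patient_id = open$patient_id,
        event_type = "followup", category = "abnormal_attention",
        detail = open$type, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(compliance) && isTRUE(compliance$low)) {
    last <- if (!is.null(state)) state$last_compliance_followup else NA
    window <- compliance$window_days
    due <- is.na(last) ||
      as.integer(compliance$as_of - as.Date(last)) >= window
    if (due) {
      ev[[length(ev) + 1L]] <- data.frame(
        date = compliance$as_of, patient_id = compliance$patient_id,
        event_type = "followup", category = "compliance",
        detail = sprintf("completion rate %.2f over %dd window",
                         compliance$rate, window),
        stringsAsFactors = FALSE)
    }
  }
  if (length(ev) == 0) return(empty_events())
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}
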