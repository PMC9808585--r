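#' @title Reading and writing the pathway's file formats
#' @name io
#' @description
#' CSV for measurements (columns patient_id,kind,value,timestamp) and event
#' logs (date,patient_id,event_type,category,detail); JSON for profiles,
#' task logs and configuration. All dates serialize as ISO 8601.
NULL

#' Read a measurement CSV
#'
#' Expects columns patient_id, kind, value, timestamp (ISO 8601). Every row
#' is validated; unit conversion is never performed (values are in the
#' kind's implied unit: mmol/L, mmHg, bpm, kg, severity grade).
#'
#' @param path CSV path.
#' @return Measurement data.frame.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "kind", "value", "timestamp")
  if (!all(needed %in% names(df))) {
    stop("measurement CSV needs columns ", paste(needed, collapse = ","),
         call. = FALSE)
  }
  bad <- !df$kind %in% MEASUREMENT_KINDS
  if (any(bad)) {
    stop("unknown measurement kind(s): ",
         paste(unique(df$kind[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$value)) || any(df$value <= 0)) {
    stop("measurement values must be positive", call. = FALSE)
  }
  df$timestamp <- as_timestamp(df$timestamp)
  df[, needed]
}

#' Write a measurement CSV
#' @param measurements Measurement data.frame.
#' @param path Output path.
#' @export
write_measurements <- function(measurements, path) {
  out <- measurements[, c("patient_id", "kind", "value", "timestamp")]
  out$timestamp <- format(as_timestamp(out$timestamp), "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE)
}

#' Read patient profiles from JSON
#' @param path Path to a JSON array of profile objects.
#' @return List of \code{patient_profile} objects.
#' @export
read_profiles <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    patient_profile(x$patient_id, x$sex, x$age,
                    diseases = unlist(x$diseases),
                    enrollment_date = x$enrollment_date,
                    special_group = unlist(x$special_group) %||% character(),
                    bmi = x$bmi %||% NA_real_,
                    smoker = isTRUE(x$smoker))
  })
}

#' Write patient profiles to JSON
#' @param profiles List of \code{patient_profile} objects.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  out <- lapply(profiles, function(p) {
    list(patient_id = p$patient_id, sex = p$sex, age = p$age,
         diseases = as.list(p$diseases),
         enrollment_date = format(p$enrollment_date),
         special_group = as.list(p$special_group),
         bmi = if (is.na(p$bmi)) NULL else p$bmi, smoker = p$smoker)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null")
}

#' Read a task log from JSON
#' @param path Path to a JSON array of task records.
#' @return Task data.frame.
#' @export
read_task_log <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  task_table(raw$patient_id, raw$task, raw$scheduled_date, raw$completed,
             raw$completed_date %||% NA)
}

#' Write a task log to JSON
#' @param tasks Task data.frame.
#' @param path Output path.
#' @export
write_task_log <- function(tasks, path) {
  out <- tasks[, c("patient_id", "task", "scheduled_date", "completed",
                   "completed_date")]
  out$scheduled_date <- format(out$scheduled_date)
  out$completed_date <- ifelse(is.na(out$completed_date), NA,
                               format(out$completed_date))
  jsonlite::write_json(out, path, auto_unbox = TRUE, na = "null",
                       dataframe = "rows")
}

#' Write an event log CSV
#' @param events Event data.frame (date, patient_id, event_type, category,
#'   detail).
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  out <- events
  out$date <- format(out$date)
  utils::write.csv(out, path, row.names = FALSE)
}

#' Read an event log CSV
#' @param path CSV path.
#' @return Event data.frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(date = "character"))
  df$date <- as.Date(df$date)
  df
}
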