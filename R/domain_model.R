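#' @title Core record types: profiles, measurements, task records, fact bases
#' @name domain_model
#' @description
#' Flat record types anchoring the pathway: a patient profile, time-stamped
#' physiological measurements, scheduled-task completion records, and the
#' per-patient fact base extracted at a decision time for rule inference.
NULL

MEASUREMENT_KINDS <- c("FBG", "PBG", "SBP", "DBP", "HR", "WEIGHT", "SYMPTOM")

# units implied by kind; never mixed (mg/dL input is rejected upstream by
# validation bounds, not converted)
MEASUREMENT_UNITS <- c(
  FBG = "mmol/L", PBG = "mmol/L", SBP = "mmHg", DBP = "mmHg",
  HR = "bpm", WEIGHT = "kg", SYMPTOM = "severity grade"
)

PATHWAY_TASKS <- list(
  regular = c("risk_assessment", "hierarchical_management",
              "self_monitoring", "regular_follow_up"),
  variation = c("abnormal_attention", "compliance_management"),
  support = c("medication_guidance", "lifestyle_guidance", "health_education")
)

#' The nine pathway tasks and their three task sets
#'
#' The management pathway defines 9 common tasks partitioned into a regular
#' management set (risk assessment, hierarchical management, self-monitoring,
#' regular follow-up), a pathway-variation set (abnormal attention,
#' compliance management) and a self-management-support set (medication
#' guidance, lifestyle guidance, health education).
#'
#' @return Named list of three character vectors (4 + 2 + 3 tasks).
#' @export
pathway_tasks <- function() PATHWAY_TASKS

#' Create a patient profile
#'
#' @param patient_id Opaque identifier string.
#' @param sex "male" or "female".
#' @param age Age in whole years (> 0).
#' @param diseases Character subset of \code{c("diabetes", "hypertension")};
#'   the pathway admits only patients with diabetes.
#' @param enrollment_date Date of entry into the management pathway.
#' @param special_group Character subset of \code{c("adolescent",
#'   "disability")}; adolescents must be under 18.
#' @param bmi Optional body-mass index (kg/m2), used by risk assessment.
#' @param smoker Optional logical smoking flag, used by risk assessment.
#' @return An object of class \code{patient_profile}.
#' @export
patient_profile <- function(patient_id, sex, age, diseases = "diabetes",
                            enrollment_date, special_group = character(),
                            bmi = NA_real_, smoker = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  age <- as.integer(age)
  diseases <- unique(as.character(diseases))
  if (!all(diseases %in% c("diabetes", "hypertension"))) {
    stop("unknown disease in profile: ",
         paste(setdiff(diseases, c("diabetes", "hypertension")), collapse = ", "),
         call. = FALSE)
  }
  if (!"diabetes" %in% diseases) {
    stop("pathway admits only patients with diabetes", call. = FALSE)
  }
  if (is.na(age) || age <= 0) stop("age must be a positive integer", call. = FALSE)
  special_group <- unique(as.character(special_group))
  if (!all(special_group %in% c("adolescent", "disability"))) {
    stop("unknown special group", call. = FALSE)
  }
  if ("adolescent" %in% special_group && age >= 18) {
    stop("adolescent special group requires age < 18", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id), sex = sex, age = age,
         diseases = diseases, enrollment_date = as.Date(enrollment_date),
         special_group = special_group, bmi = bmi, smoker = isTRUE(smoker)),
    class = "patient_profile"
  )
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile>", x$patient_id, "-", x$sex, x$age, "y;",
      paste(x$diseases, collapse = "+"),
      "; enrolled", format(x$enrollment_date), "\n")
  invisible(x)
}

#' Build a measurement table
#'
#' @param patient_id,kind,value,timestamp Vectors of equal length. Kinds are
#'   FBG/PBG (mmol/L), SBP/DBP (mmHg), HR (bpm), WEIGHT (kg), SYMPTOM
#'   (severity grade 1-3). FBG carries a pre-meal and PBG a 2-hours-after-meal
#'   context by convention; the context is metadata and is not validated.
#' @return A \code{data.frame} with columns patient_id, kind, value,
#'   timestamp (POSIXct, UTC).
#' @export
measurement_table <- function(patient_id = character(), kind = character(),
                              value = numeric(), timestamp = character()) {
  df <- data.frame(
    patient_id = as.character(patient_id),
    kind = as.character(kind),
    value = as.numeric(value),
    timestamp = as_timestamp(timestamp),
    stringsAsFactors = FALSE
  )
  df
}

as_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) return(as.POSIXct(x, tz = "UTC"))
  if (length(x) == 0) return(as.POSIXct(character(), tz = "UTC"))
  out <- as.POSIXct(as.character(x), tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%d"))
  out
}

#' Validate a single measurement record
#'
#' Returns the record unchanged when valid; signals an error for a
#' non-positive value, an unknown kind, a symptom severity outside 1-3, or a
#' timestamp before the patient's enrollment (inconsistent input).
#'
#' @param record A one-row measurement data.frame (or coercible list) with
#'   fields patient_id, kind, value, timestamp.
#' @param enrollment_date Optional enrollment date to check against.
#' @return The validated record.
#' @export
validate_record <- function(record, enrollment_date = NULL) {
  if (is.list(record) && !is.data.frame(record)) {
    record <- measurement_table(record$patient_id, record$kind,
                                record$value, record$timestamp)
  }
  stopifnot(is.data.frame(record), nrow(record) == 1)
  needed <- c("patient_id", "kind", "value", "timestamp")
  if (!all(needed %in% names(record))) {
    stop("record is missing fields: ",
         paste(setdiff(needed, names(record)), collapse = ", "), call. = FALSE)
  }
  if (!record$kind %in% MEASUREMENT_KINDS) {
    stop("unknown measurement kind: ", record$kind, call. = FALSE)
  }
  if (is.na(record$value) || record$value <= 0) {
    stop("measurement value must be positive (", record$kind, " = ",
         record$value, ")", call. = FALSE)
  }
  if (record$kind == "SYMPTOM" && !record$value %in% 1:3) {
    stop("SYMPTOM severity must be grade 1, 2 or 3", call. = FALSE)
  }
  if (!is.null(enrollment_date) &&
      as.Date(as_timestamp(record$timestamp)) < as.Date(enrollment_date)) {
    stop("measurement timestamp precedes enrollment: inconsistent input",
         call. = FALSE)
  }
  record
}

#' Build a task record table
#'
#' @param patient_id,task,scheduled_date,completed,completed_date Vectors of
#'   equal length; \code{task} must be one of the nine pathway tasks.
#' @return A \code{data.frame}; errors if a completed task lacks a completion
#'   date or was completed more than one day before schedule.
#' @export
task_table <- function(patient_id = character(), task = character(),
                       scheduled_date = character(), completed = logical(),
                       completed_date = NA) {
  all_tasks <- unlist(PATHWAY_TASKS, use.names = FALSE)
  task <- as.character(task)
  if (!all(task %in% all_tasks)) {
    stop("unknown pathway task: ",
         paste(setdiff(task, all_tasks), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    patient_id = as.character(patient_id),
    task = task,
    scheduled_date = as.Date(scheduled_date),
    completed = as.logical(completed),
    completed_date = as.Date(completed_date),
    stringsAsFactors = FALSE
  )
  bad <- df$completed & (is.na(df$completed_date) |
                           df$completed_date < df$scheduled_date - 1)
  if (any(bad)) {
    stop("completed task requires completed_date >= scheduled_date - 1 day",
         call. = FALSE)
  }
  df
}

#' Extract a patient's fact base at a decision time
#'
#' Collapses a patient's records into the ground facts the rule engine fires
#' on: latest reading per kind (\code{latest_FBG}, ...), trailing 30-day
#' means for glucose and blood pressure (\code{mean_FBG_30d}, ...), comorbid
#' hypertension, 7-day task compliance rate, days since the last completed
#' regular follow-up task, and whether a symptom was reported in the trailing
#' 7 days. Only records with timestamp <= \code{as_of} are used (no
#' lookahead). Records are ordered by timestamp with ties broken by input
#' order; two same-kind measurements at the same instant keep the last one
#' read (a warning is logged).
#'
#' @param profile A \code{patient_profile}.
#' @param records Measurement data.frame (may be empty or NULL).
#' @param tasks Task record data.frame (may be empty or NULL).
#' @param as_of Decision date.
#' @param config Pathway configuration (compliance window).
#' @return An object of class \code{factbase}: list(patient_id, as_of,
#'   facts = named list).
#' @export
build_factbase <- function(profile, records = NULL, tasks = NULL, as_of,
                           config = default_config()) {
  as_of <- as.Date(as_of)
  facts <- list(
    has_hypertension = "hypertension" %in% profile$diseases,
    age = profile$age
  )
  if (!is.na(profile$bmi)) facts$bmi <- profile$bmi
  facts$smoker <- profile$smoker

  if (!is.null(records) && nrow(records) > 0) {
    stopifnot(all(records$patient_id == profile$patient_id))
    records$timestamp <- as_timestamp(records$timestamp)
    recs <- records[as.Date(records$timestamp) <= as_of, , drop = FALSE]
    if (nrow(recs) > 0) {
      ord <- order(recs$timestamp)  # stable: ties keep input order
      recs <- recs[ord, , drop = FALSE]
      for (k in intersect(MEASUREMENT_KINDS, unique(recs$kind))) {
        sub <- recs[recs$kind == k, , drop = FALSE]
        last <- sub[nrow(sub), ]
        dup <- sum(sub$timestamp == last$timestamp)
        if (dup > 1) {
          warning("tie between ", dup, " ", k,
                  " measurements at the same instant for ",
                  profile$patient_id, "; keeping the last one read",
                  call. = FALSE)
        }
        facts[[paste0("latest_", k)]] <- last$value
      }
      win <- recs[as.Date(recs$timestamp) > as_of - 30, , drop = FALSE]
      for (k in c("FBG", "PBG", "SBP", "DBP")) {
        v <- win$value[win$kind == k]
        if (length(v) > 0) facts[[paste0("mean_", k, "_30d")]] <- mean(v)
      }
      sym <- recs[recs$kind == "SYMPTOM" &
                    as.Date(recs$timestamp) > as_of - 7, , drop = FALSE]
      facts$symptom_present <- nrow(sym) > 0
    }
  }

  if (!is.null(tasks) && nrow(tasks) > 0) {
    stopifnot(all(tasks$patient_id == profile$patient_id))
    cs <- compliance_rate(tasks, as_of,
                          window_days = config$compliance$window_days,
                          low_rate = config$compliance$low_rate)
    facts$compliance_rate_7d <- cs$rate
    done_fu <- tasks$completed_date[tasks$task == "regular_follow_up" &
                                      tasks$completed &
                                      !is.na(tasks$completed_date) &
                                      tasks$completed_date <= as_of]
    if (length(done_fu) > 0) {
      facts$days_since_last_followup <- as.integer(as_of - max(done_fu))
    }
  }

  structure(list(patient_id = profile$patient_id, as_of = as_of,
                 facts = facts),
            class = "factbase")
}

#' @export
print.factbase <- function(x, ...) {
  cat("<factbase>", x$patient_id, "as of", format(x$as_of), "—",
      length(x$facts), "facts\n")
  for (nm in names(x$facts)) {
    cat("  ", nm, "=", format(x$facts[[nm]]), "\n")
  }
  invisible(x)
}
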