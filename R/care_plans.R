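#' @title Care plan generation
#' @name care_plans
#' @description
#' The self-management-support task set: an individualized patient
#' self-management plan (monitoring scheme, medication-class guidance,
#' lifestyle advice, education topics) and a physician intervention plan
#' (regular follow-up by level, interventions for open warnings), both
#' derived from the rule base so every item is traceable to the rule that
#' produced it.
NULL

PATIENT_PLAN_TASKS <- c("self_monitoring", "medication_guidance",
                        "lifestyle_guidance", "health_education")

plan_item <- function(task, content, frequency_per_week, source_rule) {
  stopifnot(frequency_per_week > 0)
  list(task = task, content = content,
       frequency_per_week = frequency_per_week, source_rule = source_rule)
}

# static education topic list keyed by level and comorbidity; education is
# one of the nine pathway tasks but not a rule module, so these items carry
# a builtin source tag rather than a rule id
education_topics <- function(level, has_hypertension) {
  topics <- c("diabetes basics, diet and glycemic index")
  if (level >= 2) topics <- c(topics, "hypoglycemia recognition and response")
  if (level >= 3) topics <- c(topics, "intensive therapy awareness and glucose diary keeping")
  if (has_hypertension) topics <- c(topics, "home blood pressure measurement technique")
  topics
}

collect_plan_items <- function(result) {
  items <- result$multi$plan_item %||% list()
  ids <- lapply(result$trace, function(f) {
    hit <- vapply(f$assertions,
                  function(a) a$predicate == "plan_item", TRUE)
    if (!any(hit)) return(NULL)
    lapply(f$assertions[hit], function(a) list(value = a$value,
                                               rule_id = f$rule_id))
  })
  ids <- do.call(c, ids[!vapply(ids, is.null, TRUE)])
  out <- list()
  for (it in items) {
    src <- NA_character_
    for (rec in ids) {
      if (identical(rec$value, it)) { src <- rec$rule_id; break }
    }
    out[[length(out) + 1L]] <- plan_item(it$task, it$content,
                                         it$frequency_per_week, src)
  }
  out
}

#' Build the patient self-management plan
#'
#' Runs the rule base with the assigned level seeded into the facts and
#' collects the patient-role plan items: the per-level blood-glucose
#' self-monitoring scheme (defaults: level 1 one day/week, level 2 three
#' days/week, level 3 daily), daily home blood pressure iff the patient has
#' comorbid hypertension, medication-class and lifestyle guidance from rule
#' firings, and the static health-education topics for the level and
#' comorbidity. Deterministic for identical inputs.
#'
#' @param profile A \code{patient_profile}.
#' @param level Assigned management level.
#' @param facts A \code{factbase} (current decision facts).
#' @param rules A \code{rulebase}.
#' @param config Pathway configuration.
#' @return Object of class \code{care_plan} with role "patient".
#' @export
build_patient_plan <- function(profile, level, facts,
                               rules = default_rulebase(),
                               config = default_config()) {
  res <- infer(facts, rules, seed = list(management_level = as.integer(level)))
  items <- collect_plan_items(res)
  items <- Filter(function(it) it$task %in% PATIENT_PLAN_TASKS, items)
  for (topic in education_topics(level,
                                 "hypertension" %in% profile$diseases)) {
    items[[length(items) + 1L]] <- plan_item(
      "health_education", topic, 1, "builtin:health_education")
  }
  structure(list(patient_id = profile$patient_id, role = "patient",
                 level = as.integer(level),
                 issued = facts$as_of %||% Sys.Date(), items = items),
            class = "care_plan")
}

#' Build the physician intervention plan
#'
#' One regular follow-up item at the level's interval (default: level 1
#' every 90 days, levels 2-3 monthly), plus one intervention item per open
#' warning.
#'
#' @param level Management level.
#' @param config Pathway configuration.
#' @param open_warnings Optional warning data.frame of unresolved warnings.
#' @param patient_id,issued Plan metadata.
#' @return Object of class \code{care_plan} with role "physician".
#' @export
build_physician_plan <- function(level, config = default_config(),
                                 open_warnings = NULL,
                                 patient_id = NA_character_,
                                 issued = Sys.Date()) {
  iv <- interval_for_level(level, config)
  items <- list(list(
    task = "regular_follow_up",
    content = sprintf("regular follow-up for level %d patient", level),
    interval_days = iv, source_rule = NA_character_))
  if (!is.null(open_warnings) && nrow(open_warnings) > 0) {
    intervention <- c(
      BG_WARNING = "blood glucose intervention: review readings, adjust plan",
      BP_WARNING = "blood pressure intervention and antihypertensive review",
      HR_WARNING = "heart rate abnormality review",
      DISORDER_WARNING = "symptom assessment and triage")
    open <- open_warnings[!open_warnings$resolved, , drop = FALSE]
    for (ty in unique(open$type)) {
      items[[length(items) + 1L]] <- list(
        task = "abnormal_attention", content = unname(intervention[[ty]]),
        interval_days = 1L, source_rule = NA_character_)
    }
  }
  structure(list(patient_id = patient_id, role = "physician",
                 level = as.integer(level), issued = as.Date(issued),
                 items = items),
            class = "care_plan")
}

#' @export
print.care_plan <- function(x, ...) {
  cat("<care_plan>", x$role, "plan for", x$patient_id, "(level", x$level,
      ") issued", format(x$issued), "-", length(x$items), "items\n")
  for (it in x$items) {
    freq <- if (!is.null(it$frequency_per_week))
      paste0(it$frequency_per_week, "x/week") else
        paste0("every ", it$interval_days, "d")
    cat("  [", it$task, "] ", it$content, " (", freq, ")\n", sep = "")
  }
  invisible(x)
}

# drug classes that must not be recommended together; two exclusive firings
# signal a defective rule base
EXCLUSIVE_MEDICATION_ITEMS <- list(
  c("therapy intensification review", "therapy de-escalation review")
)

#' Rule-derived medication guidance
#'
#' Collects the class-level medication plan items fired by the rule base:
#' declarative drug-class suggestions only (first-line oral agent review,
#' a therapy-intensification flag at intensive level 3, antihypertensive
#' review for uncontrolled comorbid blood pressure) — never dosing numbers.
#' Two mutually exclusive suggestions firing together signal a rule-base
#' defect and raise an error.
#'
#' @param facts A \code{factbase}.
#' @param rules A \code{rulebase}.
#' @param level Optional management level to seed (when the facts alone do
#'   not determine it).
#' @return List of medication plan items (possibly empty), each with a
#'   resolvable \code{source_rule}.
#' @export
medication_guidance <- function(facts, rules = default_rulebase(),
                                level = NULL) {
  seed <- if (!is.null(level)) list(management_level = as.integer(level))
  res <- infer(facts, rules, seed = seed)
  items <- Filter(function(it) it$task == "medication_guidance",
                  collect_plan_items(res))
  contents <- vapply(items, function(it) it$content, "")
  for (pair in EXCLUSIVE_MEDICATION_ITEMS) {
    if (all(pair %in% contents)) {
      stop("contradictory medication guidance fired (", paste(pair,
           collapse = " vs "), "): rule-base defect", call. = FALSE)
    }
  }
  items
}
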