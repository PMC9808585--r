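# shared fixtures built in code

D0 <- as.Date("2024-01-01")

mk_profile <- function(id = "pt1", htn = FALSE, age = 55, sex = "female",
                       bmi = NA_real_, smoker = FALSE,
                       enrolled = D0) {
  patient_profile(id, sex, age,
                  diseases = c("diabetes", if (htn) "hypertension"),
                  enrollment_date = enrolled, bmi = bmi, smoker = smoker)
}

mk_meas <- function(pid, kind, value, day = 0, date = D0 + day) {
  measurement_table(rep(pid, length(value)), kind, value,
                    as.POSIXct(rep_len(date, length(value)), tz = "UTC"))
}

mk_facts <- function(...) {
  structure(list(patient_id = "pt1", as_of = D0, facts = list(...)),
            class = "factbase")
}

# write a rule list to a temp JSON file and load it through the package
mk_rulebase <- function(rules, config = default_config()) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(rules, path, auto_unbox = TRUE, digits = NA)
  load_rulebase(path, config = config)
}

mk_rule <- function(rule_id, conditions, actions,
                    module = "risk_assessment", provenance = "expert",
                    priority = 5) {
  list(rule_id = rule_id, module = module, provenance = provenance,
       priority = priority, conditions = conditions, actions = actions)
}

atom <- function(predicate, comparator, operand = NULL) {
  a <- list(predicate = predicate, comparator = comparator)
  if (!is.null(operand)) a$operand <- operand
  a
}

act <- function(predicate, value) list(predicate = predicate, value = value)

# full-adherence daily task log for one patient over a day range
mk_tasks <- function(pid, days, task = "self_monitoring",
                     completed = TRUE) {
  task_table(rep(pid, length(days)), rep(task, length(days)), D0 + days,
             rep_len(completed, length(days)),
             as.Date(ifelse(rep_len(completed, length(days)), D0 + days, NA),
                     origin = "1970-01-01"))
}
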