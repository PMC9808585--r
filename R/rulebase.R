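#' @title Declarative rule base and forward-chaining inference
#' @name rulebase
#' @description
#' Management knowledge is represented as condition-action rules in the
#' style of SWRL: each rule has a conjunction of atoms over patient facts
#' and asserts derived predicates (management level, warnings, plan items).
#' Rules are grouped into the ten knowledge modules of the pathway and carry
#' a provenance label (clinical expert experience, medical guidelines, or
#' both). Inference is monotone forward chaining to a fixpoint with a full
#' firing trace, so every derived assertion can be explained.
NULL

RULE_MODULES <- c(
  "diagnosis_patterns", "risk_assessment", "control_objectives",
  "hierarchical_management", "self_monitoring", "regular_follow_up",
  "abnormal_attention", "medication_guidance", "lifestyle_guidance",
  "compliance_management"
)

RULE_PROVENANCE <- c("expert", "guideline", "both")

COMPARATORS <- c("<", "<=", "=", ">=", ">", "in", "present", "absent")

#' Predicate registry
#'
#' Declares the ground (input) predicates a fact base may contain and the
#' derived predicates rules may assert. Derived predicates are disjoint from
#' input predicates; single-valued derived predicates (e.g.
#' \code{management_level}) admit one value with conflicts resolved by rule
#' priority, multi-valued ones (e.g. \code{plan_item}, \code{warning})
#' accumulate.
#'
#' @return List with character vectors \code{input}, \code{single},
#'   \code{multi}.
#' @export
predicate_registry <- function() {
  list(
    input = c(
      paste0("latest_", MEASUREMENT_KINDS),
      "mean_FBG_30d", "mean_PBG_30d", "mean_SBP_30d", "mean_DBP_30d",
      "has_hypertension", "compliance_rate_7d", "days_since_last_followup",
      "symptom_present", "age", "bmi", "smoker"
    ),
    single = c(
      "management_level", "followup_interval_days", "risk_level",
      "bg_controlled", "bp_controlled", "fbg_above_target",
      "pbg_above_target", "bp_above_target", "compliance_low"
    ),
    multi = c("warning", "plan_item", "risk_factor", "followup_due")
  )
}

#' Load and validate a rule base
#'
#' Reads a JSON array of rule objects. Each rule carries \code{rule_id},
#' \code{module} (one of the ten knowledge modules), \code{provenance}
#' (expert / guideline / both), integer \code{priority}, a nonempty
#' \code{conditions} array of atoms \code{\{predicate, comparator, operand\}}
#' and an \code{actions} array of assertions \code{\{predicate, value\}}.
#' Numeric operands and action values may be written as
#' \code{\{"ref": "targets.intensive_fbg"\}} and are resolved against the
#' configuration at load time, keeping clinical thresholds in configuration
#' rather than rule text. Rules are returned in stable order (priority
#' descending, then rule_id).
#'
#' @param path Path to a JSON rule file.
#' @param config Configuration used to resolve \code{ref} operands.
#' @param registry Predicate registry (see \code{\link{predicate_registry}}).
#' @return A list of validated rules, class \code{rulebase}.
#' @export
load_rulebase <- function(path, config = default_config(),
                          registry = predicate_registry()) {
  stopifnot(file.exists(path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(raw, resolve_refs, config = config)
  validate_rulebase(rules, registry)
}

#' The shipped default rule base
#'
#' A representative rule set covering all ten knowledge modules with
#' provenance labels, encoding the hierarchical level thresholds, control
#' objectives, risk factors, per-level self-monitoring and follow-up
#' frequencies, abnormal-attention bounds, class-level medication guidance,
#' lifestyle guidance and compliance management.
#'
#' @param config Configuration used to resolve threshold references.
#' @return A \code{rulebase}.
#' @export
default_rulebase <- function(config = default_config()) {
  load_rulebase(system.file("extdata", "rules_default.json",
                            package = "diabpath"),
                config = config)
}

resolve_refs <- function(x, config) {
  if (is.list(x)) {
    if (!is.null(x$ref) && length(x) == 1) return(config_ref(config, x$ref))
    return(lapply(x, resolve_refs, config = config))
  }
  x
}

validate_rulebase <- function(rules, registry = predicate_registry()) {
  ids <- vapply(rules, function(r) as.character(r$rule_id %||% NA), "")
  if (anyNA(ids)) stop("every rule needs a rule_id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate rule_id: ", paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "), call. = FALSE)
  }
  derived <- c(registry$single, registry$multi)
  known <- c(registry$input, derived)
  for (r in rules) {
    if (!r$module %in% RULE_MODULES) {
      stop("rule ", r$rule_id, ": unknown module '", r$module, "'",
           call. = FALSE)
    }
    if (!r$provenance %in% RULE_PROVENANCE) {
      stop("rule ", r$rule_id, ": unknown provenance '", r$provenance, "'",
           call. = FALSE)
    }
    if (length(r$conditions) == 0) {
      stop("rule ", r$rule_id, ": conditions must be nonempty", call. = FALSE)
    }
    for (a in r$conditions) {
      if (!a$predicate %in% known) {
        stop("rule ", r$rule_id, ": unknown predicate '", a$predicate, "'",
             call. = FALSE)
      }
      if (!a$comparator %in% COMPARATORS) {
        stop("rule ", r$rule_id, ": unknown comparator '", a$comparator, "'",
             call. = FALSE)
      }
      if (a$comparator %in% c("<", "<=", ">=", ">") &&
          !is.numeric(a$operand)) {
        stop("rule ", r$rule_id, ": comparator '", a$comparator,
             "' needs a numeric operand", call. = FALSE)
      }
    }
    if (length(r$actions) == 0) {
      stop("rule ", r$rule_id, ": actions must be nonempty", call. = FALSE)
    }
    for (act in r$actions) {
      if (!act$predicate %in% derived) {
        stop("rule ", r$rule_id, ": actions may assert only derived ",
             "predicates, not '", act$predicate, "'", call. = FALSE)
      }
    }
    if (is.null(r$priority)) {
      stop("rule ", r$rule_id, ": missing priority", call. = FALSE)
    }
  }
  structure(rules[rule_order(rules)], class = c("rulebase", "list"))
}

rule_order <- function(rules) {
  pri <- vapply(rules, function(r) as.numeric(r$priority), 0)
  ids <- vapply(rules, function(r) as.character(r$rule_id), "")
  order(-pri, ids)
}

#' @export
print.rulebase <- function(x, ...) {
  cat("<rulebase>", length(x), "rules across",
      length(unique(vapply(x, `[[`, "", "module"))), "modules\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atom_satisfied <- function(atom, value) {
  cmp <- atom$comparator
  if (cmp == "present") return(!is.null(value) && length(value) > 0)
  if (cmp == "absent") return(is.null(value) || length(value) == 0)
  if (is.null(value) || length(value) == 0) return(FALSE)
  op <- atom$operand
  switch(cmp,
    "<"  = any(value < op),
    "<=" = any(value <= op),
    ">=" = any(value >= op),
    ">"  = any(value > op),
    "="  = any(vapply(value, function(v) identical_value(v, op), TRUE)),
    "in" = any(value %in% unlist(op)),
    stop("unknown comparator: ", cmp, call. = FALSE)
  )
}

identical_value <- function(v, op) {
  if (is.numeric(v) && is.numeric(op)) return(isTRUE(v == op))
  if (is.logical(v) || is.logical(op)) return(isTRUE(as.logical(v) == as.logical(op)))
  identical(as.character(v), as.character(op))
}

#' Forward-chaining inference to a fixpoint
#'
#' Repeatedly applies rules (each fires at most once, on ground facts) until
#' no new assertion can be made. Derived facts are only ever added, so
#' termination is guaranteed; more than \code{max_passes} passes signals a
#' malformed rule base. When two rules assert different values for the same
#' single-valued predicate, the conflict is resolved by highest priority,
#' then lexicographically smallest rule_id: the stronger rule's value stands
#' and the weaker firing is recorded as suppressed in the trace. Permuting
#' the rule list never changes the fixpoint (rules are ordered internally).
#'
#' @param facts A \code{factbase} (or bare named list of facts).
#' @param rules A \code{rulebase}.
#' @param seed Optional named list of pre-set single-valued derived
#'   predicates (e.g. \code{list(management_level = 2)}); seeded values
#'   outrank any rule.
#' @param registry Predicate registry.
#' @param max_passes Safety bound on chaining passes.
#' @return List of class \code{inference}: \code{single} (named list),
#'   \code{multi} (named list of value lists), and \code{trace} (list of
#'   firing records with rule_id, pass, matched atoms, assertions, applied
#'   flags).
#' @export
infer <- function(facts, rules, seed = NULL,
                  registry = predicate_registry(), max_passes = 1000L) {
  fact_list <- if (inherits(facts, "factbase")) facts$facts else facts
  rules <- rules[rule_order(rules)]

  single <- list()   # predicate -> value
  single_rank <- list()  # predicate -> c(priority, rule_id) of the setter
  multi <- list()    # predicate -> list of values
  trace <- list()
  fired <- rep(FALSE, length(rules))

  if (!is.null(seed)) {
    for (nm in names(seed)) {
      single[[nm]] <- seed[[nm]]
      single_rank[[nm]] <- list(priority = Inf, rule_id = "")
    }
  }

  lookup <- function(pred) {
    if (!is.null(fact_list[[pred]])) return(fact_list[[pred]])
    if (!is.null(single[[pred]])) return(single[[pred]])
    if (!is.null(multi[[pred]])) return(multi[[pred]])
    NULL
  }

  stronger <- function(pri, id, than) {
    if (pri > than$priority) return(TRUE)
    if (pri < than$priority) return(FALSE)
    id < than$rule_id
  }

  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (pass > max_passes) {
      stop("inference did not reach a fixpoint within ", max_passes,
           " passes: malformed rule base", call. = FALSE)
    }
    changed <- FALSE
    for (i in seq_along(rules)) {
      if (fired[i]) next
      r <- rules[[i]]
      vals <- lapply(r$conditions, function(a) lookup(a$predicate))
      ok <- mapply(atom_satisfied, r$conditions, vals, SIMPLIFY = TRUE)
      if (!all(ok)) next
      fired[i] <- TRUE
      changed <- TRUE
      matched <- lapply(seq_along(r$conditions), function(j) {
        list(predicate = r$conditions[[j]]$predicate,
             comparator = r$conditions[[j]]$comparator,
             value = vals[[j]])
      })
      applied <- logical(length(r$actions))
      for (j in seq_along(r$actions)) {
        act <- r$actions[[j]]
        p <- act$predicate
        if (p %in% registry$single) {
          if (is.null(single[[p]])) {
            single[[p]] <- act$value
            single_rank[[p]] <- list(priority = as.numeric(r$priority),
                                     rule_id = as.character(r$rule_id))
            applied[j] <- TRUE
          } else if (stronger(as.numeric(r$priority),
                              as.character(r$rule_id), single_rank[[p]]) &&
                     !identical_value(single[[p]], act$value)) {
            # stronger rule overrides a weaker earlier assertion
            single[[p]] <- act$value
            single_rank[[p]] <- list(priority = as.numeric(r$priority),
                                     rule_id = as.character(r$rule_id))
            applied[j] <- TRUE
          } else if (identical_value(single[[p]], act$value)) {
            applied[j] <- TRUE
          }
        } else {
          existing <- multi[[p]] %||% list()
          dup <- any(vapply(existing, function(v) identical(v, act$value), TRUE))
          if (!dup) multi[[p]] <- c(existing, list(act$value))
          applied[j] <- TRUE
        }
      }
      trace[[length(trace) + 1L]] <- list(
        rule_id = as.character(r$rule_id), module = r$module, pass = pass,
        priority = as.numeric(r$priority), matched = matched,
        assertions = r$actions, applied = applied
      )
    }
    if (!changed) break
  }

  structure(list(single = single, multi = multi, trace = trace),
            class = "inference")
}

#' @export
print.inference <- function(x, ...) {
  cat("<inference>", length(x$trace), "rule firings;",
      length(x$single), "single-valued and",
      sum(lengths(x$multi)), "accumulated assertions\n")
  invisible(x)
}

#' Flatten the derived assertions of an inference result
#'
#' @param result An \code{inference}.
#' @return A data.frame with columns predicate and value (values collapsed
#'   to character for display; structured values are JSON-encoded).
#' @export
assertions <- function(result) {
  stopifnot(inherits(result, "inference"))
  rows <- list()
  for (nm in names(result$single)) {
    rows[[length(rows) + 1L]] <- data.frame(
      predicate = nm, value = flatten_value(result$single[[nm]]),
      stringsAsFactors = FALSE)
  }
  for (nm in names(result$multi)) {
    for (v in result$multi[[nm]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        predicate = nm, value = flatten_value(v), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(predicate = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

flatten_value <- function(v) {
  if (is.list(v)) {
    return(as.character(jsonlite::toJSON(v, auto_unbox = TRUE)))
  }
  as.character(v)
}

#' Explain a derived assertion
#'
#' Reconstructs the minimal derivation chain for an assertion from the firing
#' trace: the firing that produced it, preceded (recursively) by the firings
#' that produced any derived fact it matched on. Root causes come first.
#'
#' @param predicate Derived predicate to explain.
#' @param result An \code{inference} result.
#' @param value Optional specific value (needed for multi-valued predicates
#'   with several values).
#' @return List of steps, each \code{list(rule_id, matched)}; error if the
#'   assertion was not derived.
#' @export
explain <- function(predicate, result, value = NULL) {
  stopifnot(inherits(result, "inference"))
  reg <- predicate_registry()
  derived <- c(reg$single, reg$multi)

  # the last applied firing wins: for a single-valued predicate that is the
  # override that established the final value
  producer <- function(pred, val) {
    if (is.null(val) && pred %in% reg$single) val <- result$single[[pred]]
    for (f in rev(result$trace)) {
      for (j in seq_along(f$assertions)) {
        a <- f$assertions[[j]]
        if (a$predicate != pred || !f$applied[j]) next
        if (is.null(val) || identical(a$value, val) ||
            identical_value(a$value, val)) {
          return(f)
        }
      }
    }
    NULL
  }

  chain <- list()
  seen <- character()
  walk <- function(pred, val) {
    f <- producer(pred, val)
    if (is.null(f)) {
      stop("assertion '", pred, "' was not derived", call. = FALSE)
    }
    key <- f$rule_id
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    for (m in f$matched) {
      if (m$predicate %in% derived) {
        # recurse into supporting derived facts first
        walk(m$predicate, if (length(m$value) == 1) m$value[[1]] else NULL)
      }
    }
    chain[[length(chain) + 1L]] <<- list(rule_id = f$rule_id,
                                         matched = f$matched)
    invisible()
  }
  walk(predicate, value)
  chain
}

#' Tabulate a rule base by module and provenance
#'
#' Counts rules in each (module, provenance) cell, with per-provenance column
#' totals and each column's share of the whole base as a percentage rounded
#' half-up to one decimal.
#'
#' @param rules A \code{rulebase} (or plain list of rules).
#' @return List with \code{counts} (10 x 3 integer matrix), \code{totals}
#'   (per-provenance), \code{col_pct} (per-provenance share of all rules),
#'   and \code{n}.
#' @export
rulebase_summary <- function(rules) {
  counts <- matrix(0L, nrow = length(RULE_MODULES),
                   ncol = length(RULE_PROVENANCE),
                   dimnames = list(RULE_MODULES, RULE_PROVENANCE))
  for (r in rules) counts[r$module, r$provenance] <-
      counts[r$module, r$provenance] + 1L
  totals <- colSums(counts)
  n <- sum(totals)
  col_pct <- if (n > 0) round_half_up(100 * totals / n, 1) else totals * 0
  list(counts = counts, totals = totals, col_pct = col_pct, n = n)
}
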