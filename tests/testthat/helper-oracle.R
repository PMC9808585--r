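# independent brute-force closure oracle for small rule bases:
# repeatedly applies any applicable unfired rule in a caller-chosen scan
# order until none applies, with its own atom evaluation

oracle_atom <- function(vals, comparator, operand) {
  if (comparator == "present") return(length(vals) > 0)
  if (comparator == "absent") return(length(vals) == 0)
  if (length(vals) == 0) return(FALSE)
  for (v in vals) {
    hit <- switch(comparator,
      "<"  = v < operand,
      "<=" = v <= operand,
      ">=" = v >= operand,
      ">"  = v > operand,
      "="  = if (is.numeric(v) && is.numeric(operand)) v == operand else
        identical(as.character(v), as.character(operand)) ||
        (is.logical(v) && isTRUE(v == as.logical(operand))),
      "in" = v %in% unlist(operand),
      stop("oracle: bad comparator"))
    if (isTRUE(hit)) return(TRUE)
  }
  FALSE
}

# facts: named list of scalars; returns sorted "pred=value" strings of the
# derived closure under the given scan order
oracle_closure <- function(facts, rules, scan_order = seq_along(rules)) {
  derived <- list()  # each element list(pred, value)
  vals_of <- function(pred) {
    out <- list()
    if (!is.null(facts[[pred]])) out <- c(out, list(facts[[pred]]))
    for (d in derived) if (d$pred == pred) out <- c(out, list(d$value))
    out
  }
  applied <- rep(FALSE, length(rules))
  repeat {
    progressed <- FALSE
    for (i in scan_order) {
      if (applied[i]) next
      r <- rules[[i]]
      ok <- TRUE
      for (a in r$conditions) {
        if (!oracle_atom(vals_of(a$predicate), a$comparator, a$operand)) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      applied[i] <- TRUE
      progressed <- TRUE
      for (an in r$actions) {
        already <- any(vapply(derived, function(d) {
          d$pred == an$predicate && identical(d$value, an$value)
        }, TRUE))
        if (!already) {
          derived[[length(derived) + 1L]] <- list(pred = an$predicate,
                                                  value = an$value)
        }
      }
      break  # restart the scan after each application
    }
    if (!progressed) break
  }
  sort(vapply(derived, function(d) paste0(d$pred, "=", d$value), ""))
}

# flatten an inference result into the same sorted "pred=value" form
inference_as_set <- function(res) {
  out <- character()
  for (nm in names(res$single)) {
    out <- c(out, paste0(nm, "=", res$single[[nm]]))
  }
  for (nm in names(res$multi)) {
    for (v in res$multi[[nm]]) out <- c(out, paste0(nm, "=", v))
  }
  sort(out)
}

# generate a conflict-free random rule base (<= 8 rules) with chaining:
# actions assert multi-valued predicates with unique values, conditions mix
# numeric tests on input facts and membership tests on earlier rules' output
random_small_rulebase <- function(n_rules, seed) {
  set.seed(seed)
  multis <- c("risk_factor", "warning", "followup_due")
  rules <- list()
  made <- list()  # list of c(pred, value) already assertable
  for (i in seq_len(n_rules)) {
    conds <- list()
    conds[[1]] <- atom("latest_FBG",
                       sample(c(">", "<", ">=", "<="), 1),
                       round(stats::runif(1, 4, 14), 1))
    if (length(made) > 0 && stats::runif(1) < 0.5) {
      pick <- made[[sample(length(made), 1)]]
      conds[[2]] <- atom(pick[1], "=", pick[2])
    }
    pred <- sample(multis, 1)
    val <- paste0("v", i)
    rules[[i]] <- mk_rule(paste0("R-", sprintf("%02d", i)), conds,
                          list(act(pred, val)),
                          priority = sample(1:9, 1))
    made[[length(made) + 1L]] <- c(pred, val)
  }
  rules
}
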