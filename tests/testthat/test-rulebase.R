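test_that("the shipped rule base parses with all ten modules represented", {
  rb <- default_rulebase()
  expect_s3_class(rb, "rulebase")
  mods <- vapply(rb, `[[`, "", "module")
  expect_setequal(unique(mods),
                  c("diagnosis_patterns", "risk_assessment",
                    "control_objectives", "hierarchical_management",
                    "self_monitoring", "regular_follow_up",
                    "abnormal_attention", "medication_guidance",
                    "lifestyle_guidance", "compliance_management"))
  # stable order: priority descending, ties by rule_id
  pri <- vapply(rb, `[[`, 0, "priority")
  expect_true(all(diff(pri) <= 0))
  s <- rulebase_summary(rb)
  expect_true(all(rowSums(s$counts) > 0))
  expect_equal(sum(s$counts), length(rb))
})

test_that("rule base validation rejects malformed files", {
  r1 <- mk_rule("A-01", list(atom("latest_FBG", ">", 7)),
                list(act("risk_factor", "x")))
  expect_error(mk_rulebase(list(r1, r1)), "duplicate rule_id")
  bad_pred <- mk_rule("A-02", list(atom("no_such_fact", ">", 7)),
                      list(act("risk_factor", "x")))
  expect_error(mk_rulebase(list(bad_pred)), "unknown predicate")
  bad_mod <- mk_rule("A-03", list(atom("latest_FBG", ">", 7)),
                     list(act("risk_factor", "x")), module = "telepathy")
  expect_error(mk_rulebase(list(bad_mod)), "unknown module")
  no_cond <- mk_rule("A-04", list(), list(act("risk_factor", "x")))
  expect_error(mk_rulebase(list(no_cond)), "nonempty")
  input_action <- mk_rule("A-05", list(atom("latest_FBG", ">", 7)),
                          list(act("latest_FBG", 5)))
  expect_error(mk_rulebase(list(input_action)), "derived")
  # empty rule base is valid and inference over it is the identity
  rb0 <- mk_rulebase(list())
  expect_length(rb0, 0)
  res <- infer(mk_facts(latest_FBG = 12), rb0)
  expect_length(res$single, 0)
  expect_length(res$multi, 0)
})

test_that("inference derives intensive level 3 for fasting glucose above 11.1", {
  res <- infer(mk_facts(latest_FBG = 12.0), default_rulebase())
  expect_equal(res$single$management_level, 3)
  expect_true(any(vapply(res$trace, `[[`, "", "rule_id") == "HM-01"))
})

test_that("fixpoint equals the brute-force closure on small rule bases", {
  # hand-built 5-rule base with chaining, 4 facts
  rules <- list(
    mk_rule("C-01", list(atom("latest_FBG", ">", 7)),
            list(act("risk_factor", "hyperglycemia")), priority = 5),
    mk_rule("C-02", list(atom("has_hypertension", "=", TRUE)),
            list(act("risk_factor", "hypertension")), priority = 4),
    mk_rule("C-03", list(atom("risk_factor", "=", "hyperglycemia"),
                         atom("risk_factor", "=", "hypertension")),
            list(act("warning", "combined_risk")), priority = 3),
    mk_rule("C-04", list(atom("warning", "=", "combined_risk")),
            list(act("followup_due", "urgent")), priority = 2),
    mk_rule("C-05", list(atom("latest_HR", ">", 200)),
            list(act("warning", "never_fires")), priority = 1)
  )
  rb <- mk_rulebase(rules)
  facts <- list(latest_FBG = 9.0, has_hypertension = TRUE, age = 60,
                latest_HR = 70)
  got <- inference_as_set(infer(facts, rb))
  for (perm in list(1:5, 5:1, c(3, 1, 4, 2, 5), c(2, 4, 1, 5, 3))) {
    expect_identical(oracle_closure(facts, rules, perm), got)
  }

  # randomized conflict-free bases up to 8 rules, several scan orders each
  for (s in 1:12) {
    n <- 3 + (s %% 6)
    rules <- random_small_rulebase(n, seed = 100 + s)
    rb <- mk_rulebase(rules)
    facts <- list(latest_FBG = round(stats::runif(1, 4, 14), 1))
    got <- inference_as_set(infer(facts, rb))
    set.seed(s)
    orders <- c(list(seq_len(n), rev(seq_len(n))),
                replicate(5, sample(n), simplify = FALSE))
    for (o in orders) {
      expect_identical(oracle_closure(facts, rules, o), got)
    }
  }
})

test_that("inference is monotone in the input facts on conflict-free bases", {
  for (s in 1:8) {
    rules <- random_small_rulebase(6, seed = 200 + s)
    rb <- mk_rulebase(rules)
    base_facts <- list(latest_FBG = 8.0)
    base <- inference_as_set(infer(base_facts, rb))
    for (extra in list(list(latest_FBG = 8.0, has_hypertension = TRUE),
                       list(latest_FBG = 8.0, age = 70),
                       list(latest_FBG = 8.0, latest_HR = 130))) {
      grown <- inference_as_set(infer(extra, rb))
      expect_true(all(base %in% grown))
    }
  }
})

test_that("permuting the rule list never changes the fixpoint", {
  rb <- default_rulebase()
  fact_sets <- list(
    mk_facts(latest_FBG = 12.0, latest_PBG = 14, has_hypertension = TRUE,
             age = 65, latest_SBP = 165, latest_DBP = 95),
    mk_facts(latest_FBG = 6.0, latest_PBG = 8.0, age = 40),
    mk_facts(latest_FBG = 7.5, compliance_rate_7d = 0.2, age = 55)
  )
  for (fs in fact_sets) {
    ref <- infer(fs, rb)
    for (s in 1:4) {
      set.seed(s)
      shuffled <- structure(unclass(rb)[sample(length(rb))],
                            class = class(rb))
      res <- infer(fs, shuffled)
      expect_identical(inference_as_set(res), inference_as_set(ref))
    }
  }
})

test_that("conflicts on a single-valued predicate resolve by priority then id", {
  rules <- list(
    mk_rule("Z-low", list(atom("latest_FBG", ">", 5)),
            list(act("risk_level", "low")), priority = 1),
    mk_rule("Z-high", list(atom("latest_FBG", ">", 5)),
            list(act("risk_level", "high")), priority = 9),
    mk_rule("Z-a", list(atom("latest_FBG", ">", 5)),
            list(act("bg_controlled", FALSE)), priority = 9)
  )
  res <- infer(list(latest_FBG = 8), mk_rulebase(rules))
  expect_identical(res$single$risk_level, "high")
  # equal priority: lexicographically smallest rule_id wins
  rules2 <- list(
    mk_rule("Y-b", list(atom("latest_FBG", ">", 5)),
            list(act("risk_level", "medium")), priority = 5),
    mk_rule("Y-a", list(atom("latest_FBG", ">", 5)),
            list(act("risk_level", "apex")), priority = 5)
  )
  res2 <- infer(list(latest_FBG = 8), mk_rulebase(rules2))
  expect_identical(res2$single$risk_level, "apex")
})

test_that("explanations reconstruct minimal derivation chains", {
  rb <- default_rulebase()
  # one-step: intensive level from the fasting threshold rule
  res3 <- infer(mk_facts(latest_FBG = 12.0), rb)
  e3 <- explain("management_level", res3)
  expect_equal(e3[[length(e3)]]$rule_id, "HM-01")
  expect_equal(e3[[length(e3)]]$matched[[1]]$predicate, "latest_FBG")
  expect_equal(e3[[length(e3)]]$matched[[1]]$value, 12.0)

  # chained: controlled glucose -> level 1 is a two-element chain
  res1 <- infer(mk_facts(latest_FBG = 6.0, latest_PBG = 8.0), rb)
  e1 <- explain("management_level", res1)
  expect_equal(vapply(e1, `[[`, "", "rule_id"), c("CO-01", "HM-02"))

  expect_error(explain("warning", res1), "not derived")
})

test_that("rule-base summary counts and column shares match the taxonomy", {
  # a 192-rule base with a 44 / 83 / 65 provenance split
  prov <- c(rep("expert", 44), rep("guideline", 83), rep("both", 65))
  rules <- lapply(seq_along(prov), function(i) {
    mk_rule(sprintf("S-%03d", i), list(atom("age", ">", 0)),
            list(act("risk_factor", paste0("f", i))),
            module = rep(c("diagnosis_patterns", "risk_assessment",
                           "hierarchical_management"), length.out = 192)[i],
            provenance = prov[i])
  })
  s <- rulebase_summary(rules)
  expect_equal(s$n, 192)
  expect_equal(unname(s$totals), c(44, 83, 65))
  expect_equal(unname(s$col_pct), c(22.9, 43.2, 33.9))
  # empty base: all-zero table
  s0 <- rulebase_summary(list())
  expect_true(all(s0$counts == 0))
  expect_equal(s0$n, 0)
})
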