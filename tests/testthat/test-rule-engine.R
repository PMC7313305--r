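test_that("the generic abnormal-vital-sign rule has the fixed shape", {
  r <- gm_rule()
  expect_length(r$antecedent, 6)
  kinds <- vapply(r$antecedent, `[[`, "", "kind")
  expect_equal(kinds, c("class", "class", "property", "class", "property",
                        "class"))
  expect_equal(r$consequent$type, "assert_class")
  expect_equal(r$consequent$class_name, "AbnormalVitalSign")
  expect_equal(r$consequent$var, "?v")
  expect_silent(validate_rule(r))
})

test_that("unsafe rules are rejected", {
  expect_error(
    conjunctive_rule("bad", list(atom_class("Patient", "?p")),
                     consequent_assert_class("X", "?q")),
    "unsafe")
  expect_error(
    conjunctive_rule("empty", list(), consequent_emit_alert("A")),
    "non-empty")
})

test_that("matching a 1-observation KB yields exactly the hand-enumerated binding", {
  kb <- kb_add_patient(kb_new(), "p1")
  kb <- upsert_abnormal_range(
    kb, abnormal_range_axiom("TempAN", "Temp", interval_set(38.5, Inf)))
  kb <- assert_observation(kb, observation("o1", "p1", "Temp",
                                           "2024-01-01T00:00:00Z", 39.2))
  b <- match_rule(kb, gm_rule())
  expect_equal(nrow(b), 1)
  expect_equal(b[["?v"]], "vs:p1:Temp")
  expect_equal(b[["?o"]], "obs:o1")
  expect_equal(b[["?r"]], "res:o1")

  # normal value: no binding
  kb2 <- kb_add_patient(kb_new(), "p1")
  kb2 <- upsert_abnormal_range(
    kb2, abnormal_range_axiom("TempAN", "Temp", interval_set(38.5, Inf)))
  kb2 <- assert_observation(kb2, observation("o1", "p1", "Temp",
                                             "2024-01-01T00:00:00Z", 37.0))
  expect_equal(nrow(match_rule(kb2, gm_rule())), 0)
})

test_that("match_rule equals exhaustive assignment enumeration on random KBs", {
  for (seed in 1:30) {
    kb <- random_small_kb(seed)
    rules <- list(
      gm_rule(),
      emergency_rule_from_conditions("LOW PERF", list(c("Perf", "<", "2"))),
      emergency_rule_from_conditions("COMBO", list(
        c("Temp", ">", "3"), c("NBP_Sys", "<", "6"))))
    for (rule in rules) {
      vars <- unique(unlist(lapply(rule$antecedent, function(a)
        switch(a$kind, class = a$var,
               property = Filter(function(x) startsWith(x, "?"),
                                 c(a$subject, a$object)),
               comparison = a$var))))
      got <- bindings_canon(match_rule(kb, rule), vars)
      want <- bindings_canon(oracle_match(kb, rule), vars)
      expect_equal(got, want,
                   info = sprintf("seed %d rule %s", seed, rule$rule_id))
    }
  }
})

test_that("forward chaining reaches a fixpoint independent of rule order", {
  kb <- kb_add_patient(kb_new(), "p1")
  kb <- upsert_abnormal_range(
    kb, abnormal_range_axiom("PerfAN", "Perf", interval_set(-Inf, 0.5)))
  kb <- assert_observation(kb, observation("o1", "p1", "Perf",
                                           "2024-01-01T00:00:00Z", 0.3))
  kb <- assert_observation(kb, observation("o2", "p1", "Temp",
                                           "2024-01-01T00:00:10Z", 37))
  # a second rule chained on the first rule's derived class
  chained <- conjunctive_rule(
    "escalate", list(atom_class("AbnormalVitalSign", "?v")),
    consequent_assert_class("NeedsReview", "?v"))
  alarm <- emergency_rule_from_conditions("LOW PERF",
                                          list(c("Perf", "<", "0.5")))
  rules <- list(gm_rule(), chained, alarm)
  ref <- NULL
  for (ord in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    res <- apply_all(kb, rules[ord])
    derived <- res$kb$derived[order(res$kb$derived$class_name,
                                    res$kb$derived$individual), ]
    rownames(derived) <- NULL
    state <- list(derived = derived, alerts = sort(res$alerts$alert_id))
    if (is.null(ref)) ref <- state else expect_equal(state, ref)
  }
  expect_equal(sort(kb_derived(ref_kb <- apply_all(kb, rules)$kb,
                               "AbnormalVitalSign")), "vs:p1:Perf")
  expect_equal(kb_derived(ref_kb, "NeedsReview"), "vs:p1:Perf")
})

test_that("no rules leave the KB unchanged with an empty alert list", {
  kb <- random_small_kb(5)
  res <- apply_all(kb, list())
  expect_equal(res$kb$version, kb$version)
  expect_equal(nrow(res$alerts), 0)
  expect_equal(nrow(match_rule(kb_new(), gm_rule())), 0)
})

test_that("emergency rules bind the latest observation per sign", {
  kb <- kb_add_patient(kb_new(), "p1")
  rule <- emergency_rule_from_conditions("T HIGH", list(c("Temp", ">", "40")))
  # older reading abnormal, latest normal: must NOT fire
  kb1 <- assert_observation(kb, observation("o1", "p1", "Temp",
                                            "2024-01-01T00:00:00Z", 41))
  kb1 <- assert_observation(kb1, observation("o2", "p1", "Temp",
                                             "2024-01-01T00:00:30Z", 38))
  expect_equal(nrow(apply_all(kb1, list(rule))$alerts), 0)
  # latest abnormal: fires, evidence is the latest observation
  kb2 <- assert_observation(kb, observation("o1", "p1", "Temp",
                                            "2024-01-01T00:00:00Z", 38))
  kb2 <- assert_observation(kb2, observation("o2", "p1", "Temp",
                                             "2024-01-01T00:00:30Z", 41))
  res <- apply_all(kb2, list(rule))
  expect_equal(nrow(res$alerts), 1)
  expect_equal(res$alerts$evidence[[1]], "o2")
  expect_equal(res$alerts$label, "T HIGH")

  # a stale sign outside the co-occurrence window blocks the conjunction
  kb3 <- assert_observation(kb, observation("o1", "p1", "Temp",
                                            "2024-01-01T00:00:00Z", 41))
  kb3 <- assert_observation(kb3, observation("o2", "p1", "Perf",
                                             "2024-01-01T00:05:00Z", 0.3))
  both <- emergency_rule_from_conditions("BOTH", list(
    c("Temp", ">", "40"), c("Perf", "<", "0.5")))
  expect_equal(nrow(apply_all(kb3, list(both), window = 60)$alerts), 0)
  expect_equal(nrow(apply_all(kb3, list(both), window = 600)$alerts), 1)
})

test_that("two conditions on one sign constrain the same bound observation", {
  kb <- kb_add_patient(kb_new(), "p1")
  rule <- emergency_rule_from_conditions("BAND", list(
    c("Temp", ">", "40"), c("Temp", "<", "45")))
  expect_length(unique(vapply(
    Filter(function(a) a$kind == "comparison", rule$antecedent),
    `[[`, "", "var")), 1)
  kb1 <- assert_observation(kb, observation("o1", "p1", "Temp",
                                            "2024-01-01T00:00:00Z", 42))
  expect_equal(nrow(apply_all(kb1, list(rule))$alerts), 1)
  kb2 <- assert_observation(kb, observation("o1", "p1", "Temp",
                                            "2024-01-01T00:00:00Z", 46))
  expect_equal(nrow(apply_all(kb2, list(rule))$alerts), 0)
})

test_that("alert evidence always satisfies the installed predicate", {
  pl <- planted_emergency("LOW PERF", list(c("Perf", "<", "0.5"),
                                           c("NBP_Sys", "<", "105")),
                          episode_rate = 24, margin = 0.2)
  sim <- generate_stream(2, eval_models(), list(pl), duration_hours = 6,
                         seed = 17)
  kb <- kb_new()
  for (p in unique(sim$observations$patient_id)) kb <- kb_add_patient(kb, p)
  kb <- assert_observations(kb, sim$observations)
  rule <- emergency_rule_from_conditions("LOW PERF", list(
    c("Perf", "<", "0.5"), c("NBP_Sys", "<", "105")))
  res <- monitor_stream(kb_upsert_rule(kb, rule))
  expect_gt(nrow(res$alerts), 0)
  for (i in seq_len(nrow(res$alerts))) {
    ev <- kb$observations[kb$observations$observation_id %in%
                            res$alerts$evidence[[i]], ]
    perf <- ev$value[ev$sign_code == "Perf"]
    nbp <- ev$value[ev$sign_code == "NBP_Sys"]
    expect_true(all(perf < 0.5) && all(nbp < 105))
  }
})

test_that("rules and alerts survive JSON / JSONL round trips", {
  rules <- list(gm_rule(),
                emergency_rule_from_conditions(
                  "SpO2 LOW PERF", printed_alarm_conditions(),
                  provenance = "learned"))
  txt <- rules_to_json(rules)
  back <- rules_from_json(txt)
  expect_identical(lapply(rules, vitalwatch:::rule_to_list),
                   lapply(back, vitalwatch:::rule_to_list))
  expect_match(as.character(txt), "3749.05", fixed = TRUE)

  kb <- kb_add_patient(kb_new(), "p1")
  kb <- assert_observation(kb, observation("o1", "p1", "Temp",
                                           "2024-01-01T00:00:00Z", 41))
  rule <- emergency_rule_from_conditions("T HIGH", list(c("Temp", ">", "40")))
  res <- apply_all(kb, list(rule))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_alerts_jsonl(res$alerts, path)
  back <- read_alerts_jsonl(path)
  expect_equal(back$alert_id, res$alerts$alert_id)
  expect_equal(back$evidence, res$alerts$evidence, ignore_attr = TRUE)
  expect_equal(as.numeric(back$timestamp), as.numeric(res$alerts$timestamp))
})
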