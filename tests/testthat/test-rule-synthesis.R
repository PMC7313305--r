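test_that("the printed alarm rule converts to per-sign half-line axioms", {
  rule <- emergency_rule_from_conditions("SpO2 LOW PERF",
                                         printed_alarm_conditions())
  axs <- conditions_to_axioms(rule)
  expect_length(axs, 4)
  got <- do.call(rbind, lapply(axs, function(a)
    data.frame(class = a$class_name, sign = a$sign_code,
               lower = a$region$lower, upper = a$region$upper,
               upper_closed = a$region$upper_closed,
               stringsAsFactors = FALSE)))
  expect_equal(got$class, c("PerfAN", "AWVAN", "AWFAN", "NBP_SysAN"))
  expect_equal(got$upper, c(0.5, 3749.05, 10.4, 105))
  expect_true(all(got$lower == -Inf))
  expect_true(all(!got$upper_closed)) # strict "<" gives open bounds
  expect_true(all(vapply(axs, `[[`, "", "provenance") == "learned"))
})

test_that("operator direction and closure map onto interval regions", {
  r <- emergency_rule_from_conditions("X", list(
    c("Temp", ">", "40"), c("Perf", "<=", "0.5"), c("Pulse", ">=", "140")))
  axs <- conditions_to_axioms(r)
  expect_equal(axs[[1]]$region$lower, 40)
  expect_false(axs[[1]]$region$lower_closed)
  expect_equal(axs[[2]]$region$upper, 0.5)
  expect_true(axs[[2]]$region$upper_closed)
  expect_true(axs[[3]]$region$lower_closed)
  # two opposite bounds on one sign become disjoint half-lines after upsert
  r2 <- emergency_rule_from_conditions("Y", list(
    c("Temp", ">", "40"), c("Temp", "<", "30")))
  kb <- kb_new()
  for (a in conditions_to_axioms(r2)) kb <- upsert_abnormal_range(kb, a)
  reg <- kb$axioms$TempAN$region
  expect_equal(nrow(reg), 2)
  expect_true(oracle_in_region(reg, 25) && oracle_in_region(reg, 45))
  expect_false(oracle_in_region(reg, 35))
})

test_that("paths become rules; nominal paths are rejected", {
  p <- structure(list(
    conditions = data.frame(attribute = c("Perf", "NBP_Sys"),
                            op = c("<", "<"), value = c("0.5", "105"),
                            stringsAsFactors = FALSE),
    label = "SpO2 LOW PERF", support = 50L, purity = 1), class = "vw_tree_path")
  rule <- path_to_rule(p)
  expect_equal(rule$provenance, "learned")
  expect_equal(rule$consequent$label, "SpO2 LOW PERF")
  cond <- vitalwatch:::decode_emergency_conditions(rule)
  expect_equal(cond$sign_code, c("Perf", "NBP_Sys"))
  expect_equal(cond$value, c(0.5, 105))

  nom <- p
  nom$conditions <- data.frame(attribute = "sex", op = "=", value = "F",
                               stringsAsFactors = FALSE)
  expect_error(path_to_rule(nom), "unsupported")
})

test_that("learning on an empty alert log is a safe no-op", {
  kb <- kb_add_patient(kb_new(), "p1")
  kb <- assert_observation(kb, observation("o1", "p1", "Temp",
                                           "2024-01-01T00:00:00Z", 37))
  res <- learn_and_update(kb, learn_params(seed = 1))
  expect_length(res$report$accepted_paths, 0)
  expect_equal(length(res$kb$rules), 0)
  expect_equal(length(res$kb$axioms), 0)
  expect_gt(res$kb$version, kb$version) # run is still logged
})

test_that("the closed loop learns rules that re-detect planted episodes", {
  run <- closed_loop_run(3)
  expect_gte(run$n_learned_rules, 1)
  # every accepted path maps to one rule and at least one axiom touch
  expect_equal(length(run$report$accepted_paths),
               length(run$report$rule_ids))
  expect_gte(length(run$report$axiom_classes), 1)
  expect_gte(run$recall, 0.9)

  # learned axiom regions contain the labelled (in-episode) points: the
  # planted episode band for Perf is (0.1, 0.3]
  ax <- Filter(function(a) a$provenance == "learned",
               run$kb_trained$axioms)
  expect_gte(length(ax), 1)
  perf_ax <- run$kb_trained$axioms$PerfAN
  expect_true(all(interval_contains(perf_ax$region, c(0.15, 0.25, 0.3))))

  # loop soundness: each synthesized axiom region re-derives from the
  # operator -> interval map of its rule's conditions
  probe_point <- function(region) {
    lo <- region$lower[1]; hi <- region$upper[1]
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
    else if (is.finite(hi)) hi - 1 else lo + 1
  }
  for (rid in run$report$rule_ids) {
    rule <- run$kb_trained$rules[[rid]]
    for (a in conditions_to_axioms(rule)) {
      stored <- run$kb_trained$axioms[[a$class_name]]
      expect_true(interval_contains(stored$region, probe_point(a$region)))
    }
  }
})

test_that("GM closure: observations in newly learned regions derive abnormality", {
  run <- closed_loop_run(4)
  kb <- run$kb_trained
  kb <- kb_upsert_rule(kb, gm_rule())
  probe_pat <- names(kb$patients)[1]
  probe_t <- max(kb$observations$timestamp) + 60
  perf_hi <- kb$axioms$PerfAN$region$upper[1]
  kb <- assert_observation(kb, observation("probe1", probe_pat, "Perf",
                                           probe_t, perf_hi - 0.01))
  res <- apply_all(kb, list(gm_rule()))
  expect_true(paste0("vs:", probe_pat, ":Perf") %in%
                kb_derived(res$kb, "AbnormalVitalSign"))
})

test_that("re-learning an unchanged history never shrinks axiom regions", {
  run <- closed_loop_run(5)
  kb1 <- run$kb_trained
  regions1 <- lapply(kb1$axioms, `[[`, "region")
  res2 <- learn_and_update(kb1, learn_params(seed = 5))
  kb2 <- res2$kb
  for (cn in names(regions1)) {
    expect_true(interval_equal(kb2$axioms[[cn]]$region, regions1[[cn]]),
                label = cn)
  }
  # and the report stays audit-complete
  expect_equal(length(res2$report$accepted_paths),
               length(res2$report$rule_ids))
})

test_that("reports serialize to JSON with rejected-path reasons", {
  run <- closed_loop_run(6, duration_hours = 6)
  txt <- report_to_json(run$report)
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_equal(length(parsed$accepted_paths),
               length(run$report$accepted_paths))
  expect_true(all(c("instance_counts", "tree_size", "rule_ids") %in%
                    names(parsed)))
  # dry run computes the same report without touching the KB
  dry <- learn_and_update(run$kb_trained, learn_params(seed = 6),
                          dry_run = TRUE)
  expect_equal(dry$kb$version, run$kb_trained$version)
  expect_gte(length(dry$report$accepted_paths), 0)
})
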