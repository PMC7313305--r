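raw_table <- function() {
  data.frame(
    patient_id = "p1",
    timestamp = c("2024-01-01T00:00:00Z", "2024-01-01T00:01:00Z",
                  "2024-01-01T00:02:00Z", "2024-01-01T00:03:00Z"),
    attribute = c("Temp", "Temp", "Perf", "Perf"),
    value = c("37.0", "85", "", "0.9"),
    stringsAsFactors = FALSE)
}

test_that("outlier and missing flagging tags cells without dropping rows", {
  res <- flag_outliers_and_missing(raw_table())
  expect_equal(nrow(res$table), 4)
  # Temp = 85 outside [30, 45] is an outlier; the empty Perf is missing
  expect_equal(res$table$status, c("ok", "outlier", "missing", "ok"))
  expect_equal(res$flags$row, c(2, 3))
  expect_equal(res$flags$status, c("outlier", "missing"))

  clean <- raw_table()[c(1, 4), ]
  expect_equal(nrow(flag_outliers_and_missing(clean)$flags), 0)

  odd <- raw_table()
  odd$attribute[1] <- "Mystery"
  expect_warning(res2 <- flag_outliers_and_missing(odd), "Mystery")
  expect_equal(res2$table$status[1], "unknown")
})

test_that("flag count equals the simulator's injected missingness", {
  mods <- list(Temp = signal_model("Temp", 36.8, 0.3, period = 60,
                                   missing_rate = 0.05))
  sim <- generate_stream(1, mods, list(), duration_hours = 24, seed = 7)
  injected <- sum(is.na(sim$observations$value))
  expect_gt(injected, 0)
  raw <- data.frame(patient_id = sim$observations$patient_id,
                    timestamp = format_instant(sim$observations$timestamp),
                    attribute = sim$observations$sign_code,
                    value = ifelse(is.na(sim$observations$value), "",
                                   as.character(sim$observations$value)),
                    stringsAsFactors = FALSE)
  res <- flag_outliers_and_missing(raw)
  expect_equal(sum(res$flags$status == "missing"), injected)
})

test_that("attribute selection is lossless under restore", {
  wide <- data.frame(Perf = 1:3, NBP_Sys = 4:6, Temp = 7:9, SpO2 = 10:12,
                     AWV = 13:15, AWF = 16:18)
  sel <- select_attributes(wide, c("Perf", "NBP_Sys"))
  expect_equal(names(sel$table), c("Perf", "NBP_Sys"))
  expect_identical(restore_attributes(sel$table, sel$stash), wide)

  ident <- select_attributes(wide, names(wide))
  expect_identical(ident$table, wide)

  expect_warning(lenient <- select_attributes(wide, c("Perf", "Ghost")),
                 "Ghost")
  expect_equal(names(lenient$table), "Perf")
  expect_error(select_attributes(wide, "Ghost"), "no columns")
  expect_error(select_attributes(wide, character()), "non-empty")
})

test_that("transformation types columns and unifies dates", {
  # heterogeneous date spellings map to one canonical instant
  t <- parse_instant(c("2020-05-31", "31/05/2020", "May 31 2020"))
  expect_equal(as.numeric(t), rep(as.numeric(t[1]), 3))

  df <- data.frame(
    when = c("2020-05-31", "31/05/2020", "May 31 2020"),
    sex = c("M", "F", "M"),
    awv = c("3,749.05", "3749.05", "1200"),
    stringsAsFactors = FALSE)
  out <- transform_table(df)
  expect_equal(length(unique(out$when)), 1)
  expect_true(is.factor(out$sex))
  expect_equal(nlevels(out$sex), 2)
  expect_true(is.numeric(out$awv))
  expect_equal(out$awv[1], out$awv[2])

  # idempotence
  again <- transform_table(out)
  expect_equal(as.list(again), as.list(out))

  # untransformable cells are flagged, not raised
  bad <- data.frame(when = c("2020-05-31", "2020-06-01", "2020-06-02",
                             "not a date"), stringsAsFactors = FALSE)
  out2 <- transform_table(bad)
  expect_true(is.na(out2$when[4]))
  expect_equal(attr(out2, "flags")$row, 4)
})

toy_alert_kb <- function() {
  kb <- kb_add_patient(kb_new(), "p1")
  t0 <- "2024-01-01T00:00:00Z"
  vals <- list(SpO2 = 91, Perf = 0.3, AWV = 3000, AWF = 9, NBP_Sys = 100,
               Temp = 37, Pulse = 80)
  i <- 0
  for (s in names(vals)) {
    i <- i + 1
    kb <- assert_observation(kb, observation(paste0("o", i), "p1", s,
                                             t0, vals[[s]]))
  }
  rule <- emergency_rule_from_conditions("SpO2 LOW PERF",
                                         printed_alarm_conditions())
  kb <- kb_upsert_rule(kb, rule)
  monitor_stream(kb)$kb
}

test_that("one alert with full coverage yields one positive row of 7 features", {
  kb <- toy_alert_kb()
  expect_equal(nrow(kb$alerts), 1)
  ts <- build_training_set(kb, window = 60, seed = 1)
  pos <- ts[ts$label != "NORMAL", ]
  expect_equal(nrow(pos), 1)
  feats <- setdiff(names(ts), c("label", ".patient", ".time"))
  expect_length(feats, 7)
  expect_equal(pos$Perf, 0.3)
  expect_equal(pos$NBP_Sys, 100)
  expect_equal(pos$label, "SpO2 LOW PERF")
})

test_that("empty alert log yields an instance-free table", {
  kb <- kb_add_patient(kb_new(), "p1")
  kb <- assert_observation(kb, observation("o1", "p1", "Temp",
                                           "2024-01-01T00:00:00Z", 37))
  ts <- build_training_set(kb, seed = 1)
  expect_equal(nrow(ts), 0)
  expect_true("label" %in% names(ts))
})

test_that("positives equal planted episodes and the build is reproducible", {
  pl <- planted_emergency("LOW PERF", list(c("Perf", "<", "0.5")),
                          episode_rate = 24, margin = 0.2)
  sim <- generate_stream(2, eval_models(), list(pl), duration_hours = 12,
                         seed = 5)
  kb <- kb_new()
  for (p in unique(sim$observations$patient_id)) kb <- kb_add_patient(kb, p)
  kb <- assert_observations(kb, sim$observations)
  rule <- emergency_rule_from_conditions("LOW PERF",
                                         list(c("Perf", "<", "0.5")))
  kb <- monitor_stream(kb_upsert_rule(kb, rule))$kb
  ts1 <- build_training_set(kb, seed = 9)
  expect_equal(sum(ts1$label == "LOW PERF"), nrow(sim$annotations))
  ts2 <- build_training_set(kb, seed = 9)
  expect_identical(ts1, ts2)
  ts3 <- build_training_set(kb, seed = 10)
  expect_false(identical(ts1$.time, ts3$.time))
  # negatives are sampled 1:1 and carry no in-episode values
  expect_equal(sum(ts1$label == "NORMAL"), sum(ts1$label == "LOW PERF"))
  expect_true(all(ts1$Perf[ts1$label == "NORMAL"] >= 0.7))
})

test_that("ARFF export writes the feature and label columns", {
  pl <- planted_emergency("E", list(c("Perf", "<", "0.5")), margin = 0.2)
  df <- generate_training_fixture(pl, n_per_class = 20, seed = 2)
  path <- withr::local_tempfile(fileext = ".arff")
  write_instances_arff(df, path)
  back <- foreign::read.arff(path)
  expect_equal(nrow(back), 40)
  expect_setequal(names(back), names(df))
  expect_equal(sort(unique(as.character(back$label))), c("E", "NORMAL"))
})
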