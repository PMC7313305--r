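# Shared closed-loop monitoring scenario: 3 patients, 24 h, one planted
# two-condition emergency (low perfusion with low systolic pressure).

scenario_planted <- function() {
  planted_emergency("SpO2 LOW PERF",
                    list(c("Perf", "<", "0.5"), c("NBP_Sys", "<", "105")),
                    episode_rate = 24, episode_duration = 120, margin = 0.2)
}

scenario_kb_from_stream <- function(sim) {
  kb <- kb_new()
  for (p in sort(unique(sim$observations$patient_id)))
    kb <- kb_add_patient(kb, p)
  assert_observations(kb, sim$observations)
}

# fraction of annotated episodes covered by at least one alert of the same
# patient and label inside the episode interval
episode_recall <- function(alerts, annotations) {
  if (nrow(annotations) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    any(alerts$patient_id == a$patient_id & alerts$label == a$label &
          alerts$timestamp >= a$start & alerts$timestamp <= a$end)
  }, logical(1))
  mean(hit)
}

# one full loop: simulate -> monitor with the planted rule -> learn ->
# re-monitor a fresh stream with ONLY the learned artifacts
closed_loop_run <- function(seed, duration_hours = 24) {
  pl <- scenario_planted()
  sim <- generate_stream(3, eval_models(), list(pl),
                         duration_hours = duration_hours, seed = seed)
  kb <- scenario_kb_from_stream(sim)
  planted_rule <- emergency_rule_from_conditions(
    pl$label, pl$conditions, provenance = "seed")
  kb <- kb_upsert_rule(kb, planted_rule)
  kb <- monitor_stream(kb)$kb
  trained <- learn_and_update(kb, learn_params(seed = seed))

  learned_rules <- Filter(function(r) r$provenance == "learned",
                          trained$kb$rules)
  learned_axioms <- Filter(function(a) a$provenance == "learned",
                           trained$kb$axioms)
  sim2 <- generate_stream(3, eval_models(), list(pl),
                          duration_hours = duration_hours, seed = seed + 10000)
  kb2 <- scenario_kb_from_stream(sim2)
  for (r in learned_rules) kb2 <- kb_upsert_rule(kb2, r)
  for (a in learned_axioms) kb2 <- upsert_abnormal_range(kb2, a)
  res2 <- monitor_stream(kb2)
  list(recall = episode_recall(res2$alerts, sim2$annotations),
       n_learned_rules = length(learned_rules),
       n_episodes_train = nrow(sim$annotations),
       n_episodes_test = nrow(sim2$annotations),
       report = trained$report, kb_trained = trained$kb)
}
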