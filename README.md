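# vitalwatch

Semantic rule-based vital-sign monitoring with closed-loop rule learning.

`vitalwatch` is for clinical-informatics researchers and decision-support
engineers who want a desk-scale, fully inspectable implementation of the
loop that modern remote-monitoring systems promise: sensor observations
are classified against an ontology-shaped knowledge base by a
forward-chaining conjunctive rule engine to raise alarms, and the alarm
history is then mined with a decision-tree learner whose emergency
branches are converted back into new knowledge — conjunctive alarm rules
and per-sign abnormal-range axioms — so the knowledge base updates itself
as evidence accumulates.

## The model in brief

The knowledge base holds patients (FOAF-style person profile merged with
the health profile), sensor platforms (`hasPlatform`), a vital-sign
catalog, SOSA-style observations with results, named abnormal-range
axioms, and SWRL-style rules. The semantic core is one generic rule, *GM*:

```
VitalSign(?v) ^ Observation(?o) ^ VitalSignhasObservation(?v, ?o) ^
Result(?r) ^ hasResult(?o, ?r) ^ AbnormalRange(?r) -> AbnormalVitalSign(?v)
```

An abnormal-range axiom names a numeric region per sign — e.g. `PerfAN`,
the class of perfusion-index results with `real < 0.5` — and
`AbnormalRange` denotes the union of those regions. Learned alarm rules
are conjunctions of strict threshold conditions evaluated per patient over
the latest observation of each sign within a co-occurrence window
(default 60 s):

```
Perf < 0.5 and AWV < 3749.05 and AWF < 10.4 and NBP_Sys < 105
  -> alarm "SpO2 LOW PERF"
```

The learner (`learn_tree`) is a REPTree-style fast decision tree:
information-gain splits at midpoints between consecutive distinct values,
multiway nominal splits, reduced-error pruning on a seeded held-out
fraction. `learn_and_update` runs the whole loop — alarm history →
labelled instances → tree → high-support pure emergency paths → learned
rules and axioms, upserted (axiom regions merge by union) so that rule GM
fires on future out-of-range results.

A seeded synthetic generator (`generate_stream`) produces multi-patient
vital-sign streams with planted conjunctive emergencies and exact ground
truth, which is what the test-suite measures recall against.

## Worked example

Convert the learned low-oxygen-saturation alarm rule into per-sign
abnormal-range axioms, install them, and watch the generic rule derive an
abnormal vital sign:

```r
library(vitalwatch)

rule <- emergency_rule_from_conditions(
  "SpO2 LOW PERF",
  list(c("Perf", "<", "0.5"), c("AWV", "<", "3749.05"),
       c("AWF", "<", "10.4"), c("NBP_Sys", "<", "105")),
  provenance = "learned")

axioms <- conditions_to_axioms(rule)
for (ax in axioms) print(ax)
#> <axiom PerfAN on Perf (learned, v1): (-Inf, 0.5)>
#> <axiom AWVAN on AWV (learned, v1): (-Inf, 3749.05)>
#> <axiom AWFAN on AWF (learned, v1): (-Inf, 10.4)>
#> <axiom NBP_SysAN on NBP_Sys (learned, v1): (-Inf, 105)>

kb <- kb_add_patient(kb_new(), "p1", name = "Pat One")
for (ax in axioms) kb <- upsert_abnormal_range(kb, ax)
kb <- kb_upsert_rule(kb, gm_rule())
kb <- assert_observation(kb, observation("o1", "p1", "Perf",
                                         "2024-01-01T08:00:00Z", 0.42))
res <- apply_all(kb)
kb_derived(res$kb, "AbnormalVitalSign")
#> [1] "vs:p1:Perf"
```

Each printed axiom is a named abnormal region: `PerfAN` says a perfusion
index strictly below 0.5 is abnormal (the bound is open, so 0.5 itself is
normal). After installing the axioms, the single Perf observation at 0.42
falls into the `PerfAN` region, so forward chaining with rule GM classes
the patient's perfusion channel as an `AbnormalVitalSign`.

The full loop from the shell (see `vitalwatch help` for flags):

```sh
Rscript inst/scripts/vitalwatch.R simulate --config scenario.yaml \
    --out-obs obs.csv --out-ann truth.csv
Rscript inst/scripts/vitalwatch.R monitor --kb kb.ttl --obs obs.csv \
    --alerts alerts.jsonl --rules rules.json --create
Rscript inst/scripts/vitalwatch.R learn --kb kb.ttl --report report.json
```

The knowledge base persists as Turtle (`.ttl`), rules/trees/reports as
JSON, alerts as JSON-lines.

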