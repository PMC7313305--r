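---
title: "Semantic vital-sign monitoring and closed-loop rule learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic vital-sign monitoring and closed-loop rule learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalwatch)
```

## The monitoring model

`vitalwatch` implements a bedside-monitoring loop in which two reasoning
styles feed each other. A *semantic* layer holds an ontology-shaped
knowledge base: patients (person profile merged with the health profile),
sensor platforms linked to their owners, a vital-sign catalog, timestamped
observations with results, named *abnormal-range axioms*, and SWRL-style
conjunctive rules. A *learning* layer mines the alarm history with a fast
decision-tree learner and converts emergency tree paths back into new rules
and axioms, so the knowledge base grows as alarms accumulate.

The semantic core is a single generic rule, exposed as `gm_rule()`:

```
VitalSign(?v) ^ Observation(?o) ^ VitalSignhasObservation(?v, ?o) ^
Result(?r) ^ hasResult(?o, ?r) ^ AbnormalRange(?r) -> AbnormalVitalSign(?v)
```

`AbnormalRange` is not a stored set of individuals but the union of the
per-sign axiom regions: a result belongs to it exactly when
`classify_result()` finds its value inside any axiom region declared for
its sign. How the generic `AbnormalRange` class relates to per-sign classes
(such as `PerfAbnormalRange`) is not fixed by the ontology fragment we
model; we interpret per-sign regions as sub-regions whose union the generic
class denotes. That interpretation is deliberate and local to this package.

An abnormal-range axiom is a named region per sign — for example `PerfAN`,
the class of perfusion-index results equivalent to `real < 0.5`. Regions
are finite unions of intervals with open/closed bound tags; bounds produced
by learning are **strict** (open), so a value exactly at a learned
threshold is *not* abnormal. Updating an existing axiom takes the **union**
of old and new regions: the update operation is order-insensitive and never
forgets a previously learned abnormal region. The alternative (replacement)
would let a noisy later run silently un-learn a region; with union, wrong
regions must be retired explicitly, which we consider the safer default for
an alerting system.

## Alarm rules and temporal binding

Learned alarm rules are conjunctions of threshold conditions over several
signs, e.g. *Perf < 0.5 and AWV < 3749.05 and AWF < 10.4 and NBP_Sys <
105 → alarm "SpO2 LOW PERF"*. Measurements of different signs never share
exact timestamps in general, so a conjunction needs a temporal alignment
rule. We evaluate per patient over the **latest observation of each sign**,
and require each of those observations to lie within a configurable
co-occurrence window (default 60 s, the typical monitor sampling period) of
the patient's most recent measurement; a stale sign blocks the conjunction.
Monitor alarms describe an instantaneous patient state, which this
latest-value semantics captures without windowed aggregation.

`apply_all()` runs naive forward chaining to a fixpoint: rules assert
derived classes or emit alerts, never new individuals, so termination is
bounded by the number of derivable facts and the result is independent of
rule order. `monitor_stream()` replays a stored stream in time order and
fires an alarm rule once per *entry* into the alarm state (a rising edge),
so one planted episode yields one alert. Alerts deduplicate on (patient,
label, evidence); the refractory period beyond that is 0 by default —
re-entering the alarm state after recovery alerts again.

## Data preparation

Raw records pass through the life-cycle steps: `flag_outliers_and_missing()`
tags each cell `ok/missing/outlier/unknown` against the catalog's plausible
ranges (wide physical screens, not clinical reference ranges) without
dropping rows; `select_attributes()` is an explicit, reversible allow-list
(no automatic relevance criterion is defined for this pipeline, so we do
not invent one); `transform_table()` parses numerics (accepting
thousands-separated text such as `3,749.05`), unifies heterogeneous date
spellings to ISO-8601 UTC, and turns residual text into nominal factors,
flagging rather than raising on unconvertible cells.

`build_training_set()` turns the alert log into labelled instances: one
positive row per alert, whose features are the latest value of each
real-valued sign within the look-back window (default 60 s) before the
alert; `NORMAL` rows are sampled at a 1:1 ratio from alert-free times —
at least one window before and 300 s after any alert of the same patient.
The 300 s exclusion covers episode tails (alerts fire at episode onset, and
our episodes last minutes, not hours), keeping sampled negatives clean.
Missing features stay as explicit missing values; the learner routes them
down the larger-support branch rather than weighting fractional instances —
a documented simplification that keeps prediction deterministic.

## The tree learner

`learn_tree()` is a REPTree-style learner: splits maximize Shannon
information gain; numeric candidate thresholds are midpoints between
consecutive distinct sorted values; nominal attributes split multiway;
growing stops on purity, `min_leaf` (default 2), `max_depth`, or zero gain.
A seeded fraction of the data (default 0.25) is held out and used for
**reduced-error pruning**: bottom-up, a subtree collapses to its majority
leaf whenever held-out error does not increase, so pruning can only help or
tie on the pruning set. Ties between equal-gain splits resolve to the lower
attribute index, then the smaller threshold, making trees bit-reproducible
given data and seed. Thresholds are reported at full midpoint precision —
values like `3749.05` are midpoint artifacts, and rounding them would move
learned boundaries.

Two routing conventions matter at prediction time: a value exactly equal to
a threshold goes to the `>=` branch (consistent with the strict `<` of
learned conditions), and a missing value goes to the child with larger
training support (tie: the `<` child).

`extract_paths()` walks root-to-leaf paths, keeps leaves passing a label
filter, minimum support (default 30) and minimum purity (default 0.95),
simplifies conditions per attribute to the tightest bound per direction,
and orders paths by support. The support and purity gates are ours — the
alarm-mining procedure needs *some* acceptance bar, and 30 supporting
alarms at 95% purity is a conservative floor for promoting a pattern to an
alerting rule.

## Closing the loop

`learn_and_update()` chains the steps: training set → tree → pruning →
emergency paths → per path, one learned conjunctive alarm rule
(`path_to_rule()`) **and** one abnormal-range axiom per condition
(`conditions_to_axioms()`: `< c` becomes the open half-line `(-inf, c)`,
and symmetrically). Both artifacts are synthesized deliberately: the
conjunctive rule preserves exact alarm semantics and its label, while the
per-sign axioms feed the generic rule so any future out-of-range result
derives `AbnormalVitalSign` even outside the full conjunction. Learned
artifacts carry `provenance = "learned"` in the same store as seed and
manual knowledge; the objective/subjective distinction is a metadata tag,
not separate stores, which keeps the engine single-sourced. Every run emits
a `LearningReport` (instances per label, tree size, accepted and rejected
paths with reasons, touched rules and axioms); `--dry-run` on the CLI
computes the report without mutating the knowledge base, which is where a
human reviewer fits in.

Re-running the loop on unchanged history is idempotent at the fixpoint:
the same paths re-derive the same rules, and axiom upsert by union leaves
regions unchanged.

## The synthetic generator

`generate_stream()` emulates multi-patient monitor streams: each sign is
Gaussian around a baseline (defaults on plausible adult scales: SpO2 97 ± 1
%, Perf 2.0 ± 0.4, AWV 5000 ± 400 mL, AWF 15 ± 1.5 L/min, NBP_Sys 120 ± 8
mmHg, Temp 36.8 ± 0.3 °C, Pulse 72 ± 8 bpm), sampled every 60 s, with
optional drift, missingness and out-of-range outliers. Planted emergencies
are conjunctive predicates with a margin `m` (default 0.2 in sign units):
episode scheduling is Poisson per patient-day, episodes last 120 s and are
kept at least 5 min apart; during an episode every predicate sign is driven
into a band of width `m` hugging the threshold from the satisfying side,
and outside episodes predicate signs are reflected onto the normal side,
at least `m` away. No noise-free sample ever lies inside the open margin
band, which is what makes threshold recovery testable: any split between
the classes must fall in the empty band.

`generate_training_fixture()` builds balanced instance tables directly. Its
negatives satisfy each predicate condition independently with probability
0.25 (never all at once), so multi-condition predicates cannot be separated
by any single-feature threshold — the tree must learn the conjunction. Half
of the normal-side draws hug the band edge so midpoint thresholds land
inside the margin band rather than drifting toward the baseline bulk.

What the generator does **not** model: waveforms, physiological coupling
between signs, autocorrelated artifacts, circadian structure. Passing tests
therefore demonstrate the reasoning loop — detection, mining, knowledge
update — on signals with exact ground truth, not clinical performance on
real patients.

The seed abnormal-range catalog (`seed_axioms()`: SpO2 < 90, NBP_Sys < 90,
Temp > 38.5, Pulse outside 40–140) quantifies the classic bedside
emergencies; the defaults are package-authored starting points, clearly
marked, and not a clinical reference.

## Numerical and serialization choices

Timestamps are timezone-aware, stored UTC on a millisecond grid and
serialized ISO-8601, so text round-trips are exact. Doubles serialize with
17 significant digits (lossless). The knowledge base exports to a
restricted Turtle dialect — one fully-prefixed triple per line, one
artifact-owned namespace plus name-compatible borrowed prefixes (ICNP,
SOSA/SSN, FOAF) — that any standard Turtle parser reads, while the
package's own importer reconstructs the knowledge base exactly (versions
and ordering aside). Rules, trees and learning reports serialize to JSON;
alerts stream to JSON-lines; instance tables export to ARFF via
`foreign::write.arff` for interoperability with WEKA-style tooling.

## Problem sizes used in the shipped checks

The package's own test scenario uses 3 patients × 24 h at 60 s sampling
over the five evaluation channels, one planted two-condition emergency
(Perf < 0.5 ∧ NBP_Sys < 105, margin 0.2) at 24 episodes per patient-day
(≈ 70 episodes per run, comfortably above the default path-support gate of
30), with 20 independent seeds for the stochastic checks and n = 2000
fixtures for learner recovery. These sizes were chosen so every stochastic
property is measured on hundreds of events while a full run stays
desk-scale.

## Known limitations

Negation, disjunction and built-ins other than numeric comparison are
excluded (the rule fragment is purely conjunctive); there is no rule decay
or contradiction detection against manually authored rules; trees are
single-label classifiers; the co-occurrence window is the only temporal
construct. Nominal attributes are supported by the learner but nominal
conditions are rejected at rule synthesis (an equality over a nominal sign
has no range-axiom form) — such paths are reported as rejected rather than
silently dropped.
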