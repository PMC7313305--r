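Package: vitalwatch
Title: Semantic Rule-Based Vital-Sign Monitoring with Learned Alarm Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale health-monitoring loop combining a forward-chaining
    conjunctive rule engine over an ontology-shaped knowledge base of
    vital-sign observations with a fast decision-tree learner. Timestamped
    sensor observations are classified against named abnormal-range axioms to
    raise alerts; the alarm history is then mined with an information-gain
    tree learner (reduced-error pruning), and emergency tree paths are
    converted back into conjunctive alarm rules and per-sign abnormal-range
    axioms, closing the knowledge-update loop. Includes a seeded synthetic
    vital-sign stream generator with planted emergency episodes for ground
    truth, Turtle and JSON knowledge-base serialization, and a command-line
    driver for the simulate-ingest-monitor-learn workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    foreign,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
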