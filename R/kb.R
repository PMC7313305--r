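# The versioned knowledge base: patients, platforms, sign catalog,
# abnormal-range axioms, conjunctive rules, observations, derived class
# assertions and the append-only alert log. All mutators are functional
# (they return a new KB) and strictly increase the version counter.

empty_observations <- function() {
  data.frame(observation_id = character(), patient_id = character(),
              sign_code = character(),
              timestamp = as.POSIXct(character(), tz = "UTC"),
              value = numeric(), value_nominal = character(),
              sensor_id = character(), stringsAsFactors = FALSE)
}

empty_alerts <- function() {
  df <- data.frame(alert_id = character(), patient_id = character(),
                   timestamp = as.POSIXct(character(), tz = "UTC"),
                   label = character(), rule_id = character(),
                   stringsAsFactors = FALSE)
  df$evidence <- list()
  df
}

empty_derived <- function() {
  data.frame(class_name = character(), individual = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty knowledge base
#'
#' @param sign_catalog named list of [vital_sign()] definitions.
#' @param install_seed_axioms install the [seed_axioms()] starter catalog?
#' @return a `vw_kb` object (version 1).
#' @examples
#' kb <- kb_new()
#' kb <- kb_add_patient(kb, "p1", name = "Ada")
#' kb <- assert_observation(kb, observation("o1", "p1", "Temp",
#'                                          "2024-01-01T00:00:00Z", 37.0))
#' @export
kb_new <- function(sign_catalog = default_sign_catalog(),
                   install_seed_axioms = FALSE) {
  kb <- structure(list(
    patients = list(), platforms = list(),
    signs = sign_catalog,
    axioms = list(), rules = list(),
    observations = empty_observations(),
    derived = empty_derived(),
    alerts = empty_alerts(),
    version = 1L, log = character()
  ), class = "vw_kb")
  if (install_seed_axioms) {
    for (ax in seed_axioms()) kb <- upsert_abnormal_range(kb, ax)
  }
  kb
}

kb_bump <- function(kb, msg) {
  kb$version <- kb$version + 1L
  kb$log <- c(kb$log, sprintf("v%d %s", kb$version, msg))
  kb
}

#' @export
print.vw_kb <- function(x, ...) {
  cat(sprintf(
    "<vitalwatch knowledge base v%d>\n  patients: %d  platforms: %d  signs: %d\n  axioms: %d  rules: %d  observations: %d  alerts: %d\n",
    x$version, length(x$patients), length(x$platforms), length(x$signs),
    length(x$axioms), length(x$rules), nrow(x$observations), nrow(x$alerts)))
  invisible(x)
}

# ---- patients / platforms / signs -----------------------------------------

#' Add a patient profile
#'
#' Merges the person profile (name, birth date) with the health profile
#' (height, weight) in one record.
#'
#' @param kb knowledge base.
#' @param patient_id unique opaque identifier.
#' @param name,birth_date optional profile fields.
#' @param height_cm,weight_kg optional, strictly positive when present.
#' @return updated KB.
#' @export
kb_add_patient <- function(kb, patient_id, name = NA_character_,
                           birth_date = NA_character_,
                           height_cm = NA_real_, weight_kg = NA_real_) {
  stopifnot(inherits(kb, "vw_kb"), is.character(patient_id), nzchar(patient_id))
  if (patient_id %in% names(kb$patients))
    vw_stop("patient '%s' already exists", patient_id)
  if (!is.na(height_cm) && height_cm <= 0) vw_stop("height must be > 0")
  if (!is.na(weight_kg) && weight_kg <= 0) vw_stop("weight must be > 0")
  kb$patients[[patient_id]] <- list(
    patient_id = patient_id, name = as.character(name),
    birth_date = as.character(birth_date),
    height_cm = as.numeric(height_cm), weight_kg = as.numeric(weight_kg),
    platform_ids = character())
  kb_bump(kb, sprintf("add patient %s", patient_id))
}

#' Add a sensor platform owned by a patient
#' @param kb knowledge base.
#' @param platform_id unique identifier.
#' @param owner existing patient id.
#' @param kind one of `"body"`, `"ambient"`, `"smart_device"`.
#' @param sensor_ids non-empty character vector of sensor identifiers.
#' @return updated KB.
#' @export
kb_add_platform <- function(kb, platform_id, owner,
                            kind = c("body", "ambient", "smart_device"),
                            sensor_ids) {
  kind <- match.arg(kind)
  if (!owner %in% names(kb$patients))
    vw_stop("platform owner '%s' is not a known patient", owner)
  if (platform_id %in% names(kb$platforms))
    vw_stop("platform '%s' already exists", platform_id)
  if (length(sensor_ids) == 0) vw_stop("a platform needs at least one sensor")
  kb$platforms[[platform_id]] <- list(
    platform_id = platform_id, owner = owner, kind = kind,
    sensor_ids = as.character(sensor_ids))
  kb$patients[[owner]]$platform_ids <-
    union(kb$patients[[owner]]$platform_ids, platform_id)
  kb_bump(kb, sprintf("add platform %s", platform_id))
}

#' Add a vital-sign definition to the catalog
#' @param kb knowledge base.
#' @param def a [vital_sign()].
#' @return updated KB.
#' @export
kb_add_sign <- function(kb, def) {
  stopifnot(inherits(def, "vw_sign"))
  if (def$code %in% names(kb$signs))
    vw_stop("sign '%s' already in catalog", def$code)
  kb$signs[[def$code]] <- def
  kb_bump(kb, sprintf("add sign %s", def$code))
}

# ---- observations ----------------------------------------------------------

#' Construct an observation
#'
#' One timestamped measurement of one vital sign for one patient.
#'
#' @param observation_id unique opaque identifier.
#' @param patient_id,sign_code references into the KB.
#' @param timestamp anything accepted by [parse_instant()].
#' @param value numeric for real-valued signs, character token for nominal.
#' @param sensor_id optional sensor identifier.
#' @return a `vw_observation` list.
#' @export
observation <- function(observation_id, patient_id, sign_code, timestamp,
                        value, sensor_id = NA_character_) {
  t <- parse_instant(timestamp)
  if (is.na(t)) vw_stop("unparseable timestamp '%s'", as.character(timestamp))
  structure(list(observation_id = observation_id, patient_id = patient_id,
                 sign_code = sign_code, timestamp = t, value = value,
                 sensor_id = as.character(sensor_id)),
            class = "vw_observation")
}

obs_to_row <- function(kb, obs) {
  def <- kb$signs[[obs$sign_code]]
  if (is.null(def))
    vw_stop("unknown sign_code '%s'", obs$sign_code)
  if (!obs$patient_id %in% names(kb$patients))
    vw_stop("unknown patient '%s'", obs$patient_id)
  num <- NA_real_; nom <- NA_character_
  if (def$value_kind == "real") {
    if (!is.numeric(obs$value))
      vw_stop("sign '%s' is real-valued but value is not numeric", obs$sign_code)
    num <- as.numeric(obs$value)
  } else {
    nom <- as.character(obs$value)
  }
  row <- data.frame(observation_id = obs$observation_id,
                    patient_id = obs$patient_id, sign_code = obs$sign_code,
                    timestamp = obs$timestamp, value = num,
                    value_nominal = nom, sensor_id = obs$sensor_id,
                    stringsAsFactors = FALSE)
  row
}

#' Assert one observation into the knowledge base
#'
#' @param kb knowledge base.
#' @param obs an [observation()].
#' @return updated KB; rejects unknown patient/sign and duplicate ids.
#' @export
assert_observation <- function(kb, obs) {
  stopifnot(inherits(obs, "vw_observation"))
  if (obs$observation_id %in% kb$observations$observation_id)
    vw_stop("duplicate observation_id '%s'", obs$observation_id)
  kb$observations <- rbind(kb$observations, obs_to_row(kb, obs))
  kb_bump(kb, sprintf("assert observation %s", obs$observation_id))
}

#' Assert a batch of observations
#'
#' Vectorized ingestion of an observation table in the CSV schema
#' (`patient_id, sensor_id, sign_code, timestamp, value`) plus an
#' `observation_id` column (generated when absent). One version bump per
#' batch.
#'
#' @param kb knowledge base.
#' @param df data.frame of observations.
#' @param on_duplicate `"reject"` (error) or `"skip"` (drop already-known
#'   ids, reporting them in the `skipped` attribute of the result).
#' @return updated KB.
#' @export
assert_observations <- function(kb, df, on_duplicate = c("reject", "skip")) {
  on_duplicate <- match.arg(on_duplicate)
  if (nrow(df) == 0) return(kb)
  if (is.null(df$observation_id)) {
    df$observation_id <- sprintf("%s-%s-%06d", df$patient_id, df$sign_code,
                                 stats::ave(seq_len(nrow(df)),
                                            df$patient_id, df$sign_code,
                                            FUN = seq_along))
  }
  dup_in <- duplicated(df$observation_id)
  if (any(dup_in)) vw_stop("duplicate observation_id within batch: %s",
                           df$observation_id[dup_in][1])
  known <- df$observation_id %in% kb$observations$observation_id
  skipped <- character()
  if (any(known)) {
    if (on_duplicate == "reject")
      vw_stop("duplicate observation_id '%s'", df$observation_id[known][1])
    skipped <- df$observation_id[known]
    df <- df[!known, , drop = FALSE]
  }
  if (nrow(df) > 0) {
    bad_pat <- setdiff(unique(df$patient_id), names(kb$patients))
    if (length(bad_pat)) vw_stop("unknown patient '%s'", bad_pat[1])
    bad_sign <- setdiff(unique(df$sign_code), names(kb$signs))
    if (length(bad_sign)) vw_stop("unknown sign_code '%s'", bad_sign[1])
    kinds <- vapply(kb$signs[df$sign_code], `[[`, "", "value_kind")
    val <- if (is.numeric(df$value)) df$value else
      suppressWarnings(as.numeric(df$value))
    num <- ifelse(kinds == "real", val, NA_real_)
    nom <- ifelse(kinds == "nominal", as.character(df$value), NA_character_)
    rows <- data.frame(observation_id = as.character(df$observation_id),
                       patient_id = as.character(df$patient_id),
                       sign_code = as.character(df$sign_code),
                       timestamp = parse_instant(df$timestamp),
                       value = num, value_nominal = nom,
                       sensor_id = as.character(df$sensor_id %||%
                                                  rep(NA_character_, nrow(df))),
                       stringsAsFactors = FALSE)
    if (anyNA(rows$timestamp)) vw_stop("unparseable timestamp in batch")
    kb$observations <- rbind(kb$observations, rows)
    kb <- kb_bump(kb, sprintf("assert %d observations", nrow(rows)))
  }
  attr(kb, "skipped") <- skipped
  kb
}

#' Retrieve observations
#' @param kb knowledge base.
#' @param patient_id,sign_code optional filters.
#' @param from,to optional time-window bounds (inclusive).
#' @return data.frame of matching observations.
#' @export
kb_observations <- function(kb, patient_id = NULL, sign_code = NULL,
                            from = NULL, to = NULL) {
  df <- kb$observations
  if (!is.null(patient_id)) df <- df[df$patient_id %in% patient_id, ]
  if (!is.null(sign_code)) df <- df[df$sign_code %in% sign_code, ]
  if (!is.null(from)) df <- df[df$timestamp >= parse_instant(from), ]
  if (!is.null(to)) df <- df[df$timestamp <= parse_instant(to), ]
  rownames(df) <- NULL
  df
}

# ---- abnormal-range axioms -------------------------------------------------

#' Construct an abnormal-range axiom
#'
#' A named numeric region per vital sign: the class `<Sign>AN` (e.g.
#' `PerfAN`) holds for any observation result whose value lies in the
#' region. Learned bounds are open by default, matching the strict
#' inequalities of learned threshold conditions.
#'
#' @param class_name axiom class name (conventionally [axiom_class_name()]).
#' @param sign_code vital-sign code the region constrains.
#' @param region an [interval_set()].
#' @param provenance `"seed"`, `"learned"` or `"manual"`.
#' @param version positive integer, bumped on every upsert of the class.
#' @param created_at creation instant.
#' @return a `vw_axiom` object.
#' @export
abnormal_range_axiom <- function(class_name, sign_code, region,
                                 provenance = c("manual", "seed", "learned"),
                                 version = 1L,
                                 created_at = "2024-01-01T00:00:00Z") {
  provenance <- match.arg(provenance)
  region <- interval_normalize(region)
  if (nrow(region) == 0) vw_stop("axiom region must be non-empty")
  structure(list(class_name = class_name, sign_code = sign_code,
                 region = region, provenance = provenance,
                 version = as.integer(version),
                 created_at = parse_instant(created_at)),
            class = "vw_axiom")
}

#' @export
print.vw_axiom <- function(x, ...) {
  ivs <- apply(as.data.frame(x$region), 1, function(r) {
    sprintf("%s%s, %s%s",
            if (as.logical(r[["lower_closed"]])) "[" else "(",
            r[["lower"]], r[["upper"]],
            if (as.logical(r[["upper_closed"]])) "]" else ")")
  })
  cat(sprintf("<axiom %s on %s (%s, v%d): %s>\n", x$class_name, x$sign_code,
              x$provenance, x$version, paste(ivs, collapse = " u ")))
  invisible(x)
}

#' Insert or update an abnormal-range axiom
#'
#' If an axiom with the same class name exists, the stored region becomes
#' the union of old and new regions (update never forgets a previously
#' learned abnormal region and is order-insensitive) and the axiom version
#' is bumped; otherwise the axiom is inserted as given.
#'
#' @param kb knowledge base.
#' @param ax an [abnormal_range_axiom()].
#' @return updated KB.
#' @export
upsert_abnormal_range <- function(kb, ax) {
  stopifnot(inherits(ax, "vw_axiom"))
  if (!ax$sign_code %in% names(kb$signs))
    vw_stop("axiom '%s' refers to unknown sign '%s'", ax$class_name, ax$sign_code)
  old <- kb$axioms[[ax$class_name]]
  if (!is.null(old)) {
    if (old$sign_code != ax$sign_code)
      vw_stop("axiom class '%s' already bound to sign '%s'",
              ax$class_name, old$sign_code)
    ax$region <- interval_union(old$region, ax$region)
    ax$version <- old$version + 1L
    ax$created_at <- old$created_at
  }
  kb$axioms[[ax$class_name]] <- ax
  kb_bump(kb, sprintf("upsert axiom %s (v%d)", ax$class_name, ax$version))
}

#' Classify a result value as abnormal or not
#'
#' `TRUE` iff the value lies in the union of the regions of all
#' abnormal-range axioms declared for the sign. A sign with no axiom yields
#' `FALSE` for every value.
#'
#' @param kb knowledge base.
#' @param sign_code real-valued sign.
#' @param value numeric vector.
#' @return logical vector.
#' @export
classify_result <- function(kb, sign_code, value) {
  def <- kb$signs[[sign_code]]
  if (is.null(def)) vw_stop("unknown sign_code '%s'", sign_code)
  if (def$value_kind != "real")
    vw_stop("sign '%s' is nominal: numeric abnormal-range classification unsupported",
            sign_code)
  hit <- rep(FALSE, length(value))
  for (ax in kb$axioms) {
    if (ax$sign_code == sign_code)
      hit <- hit | interval_contains(ax$region, value)
  }
  hit
}

# ---- rules & alerts (storage; semantics live in rules.R / engine.R) --------

#' Insert or replace a conjunctive rule
#' @param kb knowledge base.
#' @param rule a `vw_rule` (see [conjunctive_rule()]).
#' @return updated KB.
#' @export
kb_upsert_rule <- function(kb, rule) {
  stopifnot(inherits(rule, "vw_rule"))
  validate_rule(rule)
  kb$rules[[rule$rule_id]] <- rule
  kb_bump(kb, sprintf("upsert rule %s", rule$rule_id))
}

kb_append_alerts <- function(kb, alerts) {
  if (nrow(alerts) == 0) return(kb)
  new <- !alerts$alert_id %in% kb$alerts$alert_id
  if (!any(new)) return(kb)
  kb$alerts <- rbind(kb$alerts, alerts[new, , drop = FALSE])
  kb_bump(kb, sprintf("append %d alerts", sum(new)))
}

# ---- integrity validator (used by tests) ----------------------------------

#' Validate knowledge-base invariants
#'
#' Checks referential integrity, axiom-region normalization, alert evidence
#' resolution and value-kind consistency; errors on the first violation.
#'
#' @param kb knowledge base.
#' @return `TRUE` invisibly.
#' @export
kb_validate <- function(kb) {
  for (pl in kb$platforms) {
    if (!pl$owner %in% names(kb$patients))
      vw_stop("platform '%s' owner missing", pl$platform_id)
  }
  obs <- kb$observations
  if (!all(obs$patient_id %in% names(kb$patients)))
    vw_stop("observation with unknown patient")
  if (!all(obs$sign_code %in% names(kb$signs)))
    vw_stop("observation with unknown sign")
  kinds <- vapply(kb$signs[obs$sign_code], `[[`, "", "value_kind")
  if (any(kinds == "real" & is.na(obs$value) & !is.na(obs$value_nominal)))
    vw_stop("nominal value stored for real sign")
  for (ax in kb$axioms) {
    if (!ax$sign_code %in% names(kb$signs))
      vw_stop("axiom '%s' sign missing", ax$class_name)
    if (!interval_is_normalized(ax$region))
      vw_stop("axiom '%s' region not normalized", ax$class_name)
  }
  for (i in seq_len(nrow(kb$alerts))) {
    ev <- kb$alerts$evidence[[i]]
    if (length(ev) == 0) vw_stop("alert without evidence")
    if (!kb$alerts$rule_id[i] %in% names(kb$rules))
      vw_stop("alert fired by unknown rule '%s'", kb$alerts$rule_id[i])
    if (!all(ev %in% obs$observation_id))
      vw_stop("alert evidence does not resolve")
  }
  invisible(TRUE)
}
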