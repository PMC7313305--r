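# Vital-sign catalog and seed abnormal-range axioms.

#' Define a vital sign
#'
#' @param code short symbolic name, e.g. `"Perf"`, `"NBP_Sys"`.
#' @param unit measurement unit text (may be empty).
#' @param value_kind `"real"` or `"nominal"`.
#' @param plausible_lower,plausible_upper optional closed plausibility bounds
#'   used only for outlier flagging in data preparation; these are broad
#'   engineering screens, not clinical reference ranges.
#' @return a `vw_sign` list.
#' @export
vital_sign <- function(code, unit = "", value_kind = c("real", "nominal"),
                       plausible_lower = NA_real_, plausible_upper = NA_real_) {
  value_kind <- match.arg(value_kind)
  stopifnot(is.character(code), nzchar(code))
  structure(list(code = code, unit = unit, value_kind = value_kind,
                 plausible_lower = as.numeric(plausible_lower),
                 plausible_upper = as.numeric(plausible_upper)),
            class = "vw_sign")
}

#' Default vital-sign catalog
#'
#' The seven monitored channels: pulse-oximetry oxygen saturation (SpO2) and
#' perfusion index (Perf), ventilator airway volume (AWV) and airway flow
#' (AWF), non-invasive systolic blood pressure (NBP_Sys), body temperature
#' (Temp) and pulse rate (Pulse). Plausibility bounds are wide physical
#' screens for outlier flagging.
#'
#' @return named list of [vital_sign()] definitions.
#' @export
default_sign_catalog <- function() {
  defs <- list(
    vital_sign("SpO2",    "%",      "real", 0,   100),
    vital_sign("Perf",    "",       "real", 0,   20),
    vital_sign("AWV",     "mL",     "real", 0,   10000),
    vital_sign("AWF",     "L/min",  "real", 0,   120),
    vital_sign("NBP_Sys", "mmHg",   "real", 30,  300),
    vital_sign("Temp",    "degC",   "real", 30,  45),
    vital_sign("Pulse",   "bpm",    "real", 20,  250)
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "code"))
}

#' Canonical abnormal-range class name for a sign
#'
#' Class names follow the `<SignCode>AN` convention (e.g. `PerfAN`).
#' @param sign_code vital-sign code.
#' @return character class name.
#' @export
axiom_class_name <- function(sign_code) paste0(sign_code, "AN")

#' Seed abnormal-range axioms
#'
#' A small starter catalog covering the classic bedside emergencies (low
#' oxygen saturation, low systolic pressure, fever, brady-/tachycardia).
#' These defaults are package-authored starting points meant to be replaced
#' or extended by learned axioms; they are not a clinical reference.
#'
#' @return list of [abnormal_range_axiom()] objects with provenance `"seed"`.
#' @export
seed_axioms <- function() {
  list(
    abnormal_range_axiom("SpO2AN", "SpO2", interval_set(-Inf, 90),
                         provenance = "seed"),
    abnormal_range_axiom("NBP_SysAN", "NBP_Sys", interval_set(-Inf, 90),
                         provenance = "seed"),
    abnormal_range_axiom("TempAN", "Temp", interval_set(38.5, Inf),
                         provenance = "seed"),
    abnormal_range_axiom("PulseAN", "Pulse",
                         interval_set(c(-Inf, 140), c(40, Inf)),
                         provenance = "seed")
  )
}
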