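# SWRL-style conjunctive rules: class atoms, property atoms and numeric
# comparison atoms over variables bound to individuals of the knowledge
# base. Variables are "?"-prefixed tokens; any other argument of a property
# atom is a constant.

#' Rule atoms
#'
#' @param class_name,property ontology class / property name.
#' @param var,subject,object symbolic variable tokens (`"?v"`) or, for
#'   property arguments, constants.
#' @param op comparison operator, one of `<`, `<=`, `>`, `>=`, `=`.
#' @param const finite numeric constant.
#' @return a `vw_atom` list.
#' @export
atom_class <- function(class_name, var) {
  structure(list(kind = "class", class_name = class_name, var = var),
            class = "vw_atom")
}

#' @rdname atom_class
#' @export
atom_property <- function(property, subject, object) {
  structure(list(kind = "property", property = property,
                 subject = subject, object = object),
            class = "vw_atom")
}

#' @rdname atom_class
#' @export
atom_comparison <- function(var, op, const) {
  stopifnot(op %in% c("<", "<=", ">", ">=", "="), is.finite(const))
  structure(list(kind = "comparison", var = var, op = op,
                 const = as.numeric(const)),
            class = "vw_atom")
}

is_var <- function(x) is.character(x) && length(x) == 1 && startsWith(x, "?")

atom_vars <- function(atom) {
  switch(atom$kind,
    class = atom$var,
    property = c(atom$subject, atom$object)[c(is_var(atom$subject),
                                              is_var(atom$object))],
    comparison = atom$var)
}

#' Construct a conjunctive rule
#'
#' A safe Horn rule: every variable of the consequent must occur in the
#' antecedent, and the antecedent is non-empty.
#'
#' @param rule_id unique identifier.
#' @param antecedent list of atoms ([atom_class()], [atom_property()],
#'   [atom_comparison()]).
#' @param consequent either `consequent_assert_class(class_name, var)` or
#'   `consequent_emit_alert(label)`.
#' @param label optional alarm label text.
#' @param provenance `"seed"`, `"learned"` or `"manual"`.
#' @param enabled is the rule active for the engine?
#' @return a `vw_rule` object.
#' @export
conjunctive_rule <- function(rule_id, antecedent, consequent,
                             label = NA_character_,
                             provenance = c("manual", "seed", "learned"),
                             enabled = TRUE) {
  provenance <- match.arg(provenance)
  rule <- structure(list(rule_id = rule_id, label = as.character(label),
                         antecedent = antecedent, consequent = consequent,
                         provenance = provenance, enabled = enabled),
                    class = "vw_rule")
  validate_rule(rule)
  rule
}

#' @rdname conjunctive_rule
#' @param class_name class to assert on `var`.
#' @param var consequent variable.
#' @export
consequent_assert_class <- function(class_name, var) {
  list(type = "assert_class", class_name = class_name, var = var)
}

#' @rdname conjunctive_rule
#' @export
consequent_emit_alert <- function(label) {
  list(type = "emit_alert", label = label)
}

#' Check rule safety
#'
#' Errors unless the antecedent is non-empty and every consequent variable
#' is bound by an antecedent atom.
#' @param rule a `vw_rule`.
#' @return `TRUE` invisibly.
#' @export
validate_rule <- function(rule) {
  if (length(rule$antecedent) == 0) vw_stop("rule antecedent must be non-empty")
  bound <- unique(unlist(lapply(rule$antecedent, atom_vars)))
  if (rule$consequent$type == "assert_class" &&
      !rule$consequent$var %in% bound)
    vw_stop("unsafe rule: consequent variable %s unbound", rule$consequent$var)
  invisible(TRUE)
}

#' The generic abnormal-vital-sign rule (rule GM)
#'
#' For a vital sign `?v` with observation `?o` whose result `?r` lies in an
#' abnormal range, derive that `?v` is an abnormal vital sign:
#'
#' `VitalSign(?v) ^ Observation(?o) ^ VitalSignhasObservation(?v,?o) ^
#'  Result(?r) ^ hasResult(?o,?r) ^ AbnormalRange(?r) -> AbnormalVitalSign(?v)`
#'
#' @return a `vw_rule` with six antecedent atoms.
#' @export
gm_rule <- function() {
  conjunctive_rule(
    rule_id = "GM",
    antecedent = list(
      atom_class("VitalSign", "?v"),
      atom_class("Observation", "?o"),
      atom_property("VitalSignhasObservation", "?v", "?o"),
      atom_class("Result", "?r"),
      atom_property("hasResult", "?o", "?r"),
      atom_class("AbnormalRange", "?r")
    ),
    consequent = consequent_assert_class("AbnormalVitalSign", "?v"),
    provenance = "seed"
  )
}

#' Build an emergency alarm rule from threshold conditions
#'
#' The rule binds, per distinct sign, the patient's most recent observation
#' of that sign (within the engine's co-occurrence window) and emits an
#' alert labelled `label` when every condition holds. Two conditions on the
#' same sign constrain the same bound observation (conjunction).
#'
#' @param label alarm label, e.g. `"SpO2 LOW PERF"`.
#' @param conditions data.frame with columns `sign_code` (or `attribute`),
#'   `op` in `<`, `<=`, `>`, `>=`, and `value`; or a list of 3-element
#'   vectors/lists `(sign, op, value)`.
#' @param rule_id identifier; default is derived from label and conditions.
#' @param provenance rule provenance tag.
#' @return a `vw_rule` emitting the alert.
#' @examples
#' r <- emergency_rule_from_conditions("SpO2 LOW PERF", list(
#'   c("Perf", "<", "0.5"), c("AWV", "<", "3749.05"),
#'   c("AWF", "<", "10.4"), c("NBP_Sys", "<", "105")))
#' @export
emergency_rule_from_conditions <- function(label, conditions,
                                           rule_id = NULL,
                                           provenance = "manual") {
  cond <- normalize_conditions(conditions)
  if (nrow(cond) == 0) vw_stop("conditions must be non-empty")
  if (!all(cond$op %in% c("<", "<=", ">", ">=")))
    vw_stop("emergency conditions allow only <, <=, >, >=")
  atoms <- list(atom_class("Patient", "?p"))
  for (s in unique(cond$sign_code)) {
    v <- paste0("?o_", s)
    atoms <- c(atoms, list(
      atom_property("latestObservation", "?p", v),
      atom_property("observedProperty", v, s)))
  }
  for (i in seq_len(nrow(cond))) {
    atoms <- c(atoms, list(
      atom_comparison(paste0("?o_", cond$sign_code[i]),
                      cond$op[i], cond$value[i])))
  }
  if (is.null(rule_id)) {
    rule_id <- paste0("alarm:", gsub("\\s+", "_", label), ":",
                      paste(sprintf("%s%s%s", cond$sign_code, cond$op,
                                    vapply(cond$value, format, "",
                                           digits = 15)),
                            collapse = ","))
  }
  conjunctive_rule(rule_id, atoms, consequent_emit_alert(label),
                   label = label, provenance = provenance)
}

normalize_conditions <- function(conditions) {
  if (is.data.frame(conditions)) {
    sign <- conditions$sign_code %||% conditions$attribute
    df <- data.frame(sign_code = as.character(sign),
                     op = as.character(conditions$op),
                     value = as.numeric(conditions$value),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(conditions, function(cd) {
      cd <- as.list(cd)
      data.frame(sign_code = as.character(cd[[1]]), op = as.character(cd[[2]]),
                 value = as.numeric(cd[[3]]), stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(sign_code = character(),
                                      op = character(), value = numeric())
  }
  if (any(!is.finite(df$value))) vw_stop("condition constants must be finite")
  df
}

# recover (sign, op, value) conditions from an emergency-form rule;
# NULL if the rule does not follow the emergency_rule_from_conditions shape
decode_emergency_conditions <- function(rule) {
  if (rule$consequent$type != "emit_alert") return(NULL)
  sign_of_var <- list()
  for (a in rule$antecedent) {
    if (a$kind == "property" && a$property == "observedProperty" &&
        is_var(a$subject) && !is_var(a$object)) {
      sign_of_var[[a$subject]] <- a$object
    }
  }
  conds <- list()
  for (a in rule$antecedent) {
    if (a$kind == "comparison") {
      s <- sign_of_var[[a$var]]
      if (is.null(s)) return(NULL)
      conds[[length(conds) + 1]] <-
        data.frame(sign_code = s, op = a$op, value = a$const,
                   stringsAsFactors = FALSE)
    }
  }
  ok_kinds <- vapply(rule$antecedent, function(a) {
    a$kind == "comparison" ||
      (a$kind == "class" && a$class_name == "Patient") ||
      (a$kind == "property" &&
         a$property %in% c("latestObservation", "observedProperty"))
  }, logical(1))
  if (!all(ok_kinds) || length(conds) == 0) return(NULL)
  do.call(rbind, conds)
}

# ---- human-readable and JSON forms ----------------------------------------

atom_text <- function(a) {
  switch(a$kind,
    class = sprintf("%s(%s)", a$class_name, a$var),
    property = sprintf("%s(%s, %s)", a$property, a$subject, a$object),
    comparison = sprintf("%s %s %s", a$var, a$op, format(a$const)))
}

#' Render a rule in SWRL-like text
#' @param rule a `vw_rule`.
#' @return single character string.
#' @export
rule_text <- function(rule) {
  lhs <- paste(vapply(rule$antecedent, atom_text, ""), collapse = " ^ ")
  rhs <- if (rule$consequent$type == "assert_class") {
    sprintf("%s(%s)", rule$consequent$class_name, rule$consequent$var)
  } else {
    sprintf("Alert(\"%s\")", rule$consequent$label)
  }
  paste(lhs, "->", rhs)
}

#' @export
print.vw_rule <- function(x, ...) {
  cat(sprintf("<rule %s (%s%s)>\n  %s\n", x$rule_id, x$provenance,
              if (x$enabled) "" else ", disabled", rule_text(x)))
  invisible(x)
}

rule_to_list <- function(rule) {
  list(rule_id = rule$rule_id, label = rule$label,
       antecedent = lapply(rule$antecedent, unclass),
       consequent = rule$consequent,
       provenance = rule$provenance, enabled = rule$enabled)
}

rule_from_list <- function(x) {
  atoms <- lapply(x$antecedent, function(a) {
    a <- as.list(a)
    switch(a$kind,
      class = atom_class(a$class_name, a$var),
      property = atom_property(a$property, a$subject, a$object),
      comparison = atom_comparison(a$var, a$op, as.numeric(a$const)),
      vw_stop("unknown atom kind '%s'", a$kind))
  })
  cons <- as.list(x$consequent)
  conjunctive_rule(x$rule_id, atoms, cons,
                   label = x$label %||% NA_character_,
                   provenance = x$provenance %||% "manual",
                   enabled = isTRUE(x$enabled %||% TRUE))
}

#' Serialize rules to / from JSON
#'
#' @param rules list of `vw_rule` objects (or a single rule).
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return `rules_to_json`: JSON text (invisibly when written to a file);
#'   `rules_from_json`: list of `vw_rule`.
#' @export
rules_to_json <- function(rules, path = NULL) {
  if (inherits(rules, "vw_rule")) rules <- list(rules)
  txt <- jsonlite::toJSON(lapply(rules, rule_to_list),
                          auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname rules_to_json
#' @param x JSON text or a file path to read.
#' @export
rules_from_json <- function(x) {
  if (length(x) == 1 && file.exists(x)) x <- paste(readLines(x), collapse = "\n")
  parsed <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  lapply(parsed, rule_from_list)
}
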