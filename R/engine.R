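# Rule matcher and forward-chaining engine.
#
# The instance graph is induced from KB tables: each patient is an
# individual "pat:<id>"; each observed (patient, sign) pair a vital-sign
# individual "vs:<patient>:<sign>"; each observation "obs:<id>" with result
# "res:<id>" carrying the numeric value. Rules never create individuals, so
# naive iteration to fixpoint terminates.

IND_PAT <- "pat:"; IND_VS <- "vs:"; IND_OBS <- "obs:"; IND_RES <- "res:"

ind_strip <- function(x, prefix) substring(x, nchar(prefix) + 1)

# paste0 that returns character(0) when any part is empty (base paste0
# treats zero-length vectors as "")
zpaste <- function(...) {
  args <- list(...)
  if (any(vapply(args, length, 0L) == 0)) return(character(0))
  paste0(...)
}

# latest observation per (patient, sign), restricted to those within
# `window` seconds of the reference time (per patient by default)
latest_obs_table <- function(kb, window = 60, t_ref = NULL) {
  obs <- kb$observations
  if (nrow(obs) == 0) return(obs)
  ord <- order(obs$patient_id, obs$sign_code, obs$timestamp)
  obs <- obs[ord, , drop = FALSE]
  last <- !duplicated(paste(obs$patient_id, obs$sign_code), fromLast = TRUE)
  latest <- obs[last, , drop = FALSE]
  if (is.null(t_ref)) {
    ref <- tapply(as.numeric(kb$observations$timestamp),
                  kb$observations$patient_id, max)
    refs <- ref[latest$patient_id]
  } else {
    refs <- rep(as.numeric(parse_instant(t_ref)), nrow(latest))
  }
  keep <- (refs - as.numeric(latest$timestamp)) <= window
  latest[keep, , drop = FALSE]
}

class_members <- function(kb, class_name, window, t_ref) {
  obs <- kb$observations
  switch(class_name,
    Patient = zpaste(IND_PAT, names(kb$patients)),
    VitalSign = {
      u <- unique(obs[c("patient_id", "sign_code")])
      zpaste(IND_VS, u$patient_id, ":", u$sign_code)
    },
    Observation = zpaste(IND_OBS, obs$observation_id),
    Result = zpaste(IND_RES, obs$observation_id),
    AbnormalRange = {
      hit <- rep(FALSE, nrow(obs))
      for (ax in kb$axioms) {
        sel <- obs$sign_code == ax$sign_code
        if (any(sel))
          hit[sel] <- hit[sel] | interval_contains(ax$region, obs$value[sel])
      }
      zpaste(IND_RES, obs$observation_id[hit])
    },
    {
      ax <- kb$axioms[[class_name]]
      if (!is.null(ax)) {
        sel <- obs$sign_code == ax$sign_code &
          interval_contains(ax$region, obs$value)
        return(zpaste(IND_RES, obs$observation_id[sel]))
      }
      if (class_name == "AbnormalVitalSign" ||
          class_name %in% kb$derived$class_name ||
          any(vapply(kb$rules, function(r)
            r$consequent$type == "assert_class" &&
              r$consequent$class_name == class_name, logical(1)))) {
        return(kb$derived$individual[kb$derived$class_name == class_name])
      }
      vw_stop("unknown class '%s' in rule atom", class_name)
    })
}

property_pairs <- function(kb, property, window, t_ref) {
  obs <- kb$observations
  switch(property,
    VitalSignhasObservation = data.frame(
      subject = zpaste(IND_VS, obs$patient_id, ":", obs$sign_code),
      object = zpaste(IND_OBS, obs$observation_id),
      stringsAsFactors = FALSE),
    hasResult = data.frame(
      subject = zpaste(IND_OBS, obs$observation_id),
      object = zpaste(IND_RES, obs$observation_id),
      stringsAsFactors = FALSE),
    observedProperty = data.frame(
      subject = zpaste(IND_OBS, obs$observation_id),
      object = obs$sign_code, stringsAsFactors = FALSE),
    latestObservation = {
      lt <- latest_obs_table(kb, window, t_ref)
      data.frame(subject = zpaste(IND_PAT, lt$patient_id),
                 object = zpaste(IND_OBS, lt$observation_id),
                 stringsAsFactors = FALSE)
    },
    hasPlatform = {
      if (length(kb$platforms) == 0)
        return(data.frame(subject = character(), object = character()))
      do.call(rbind, lapply(kb$platforms, function(pl)
        data.frame(subject = paste0(IND_PAT, pl$owner),
                   object = paste0("plat:", pl$platform_id),
                   stringsAsFactors = FALSE)))
    },
    vw_stop("unknown property '%s' in rule atom", property))
}

# numeric value carried by an individual (result or observation)
value_of_individuals <- function(kb, ids) {
  out <- rep(NA_real_, length(ids))
  is_res <- startsWith(ids, IND_RES)
  is_obs <- startsWith(ids, IND_OBS)
  key <- ifelse(is_res, ind_strip(ids, IND_RES),
                ifelse(is_obs, ind_strip(ids, IND_OBS), NA))
  m <- match(key, kb$observations$observation_id)
  out[!is.na(m)] <- kb$observations$value[m[!is.na(m)]]
  out
}

#' Match a conjunctive rule against the knowledge base
#'
#' Returns exactly the variable bindings under which every antecedent atom
#' holds; no side effects. Range-class atoms (e.g. `AbnormalRange`,
#' `PerfAN`) evaluate through the axiom regions as in [classify_result()].
#'
#' @param kb knowledge base.
#' @param rule a `vw_rule`.
#' @param window co-occurrence window in seconds for `latestObservation`
#'   atoms (how stale a sign's last measurement may be).
#' @param t_ref optional evaluation instant; default is each patient's
#'   latest observation time.
#' @return data.frame with one column per variable (individual ids such as
#'   `"obs:o1"`), one row per binding.
#' @export
match_rule <- function(kb, rule, window = 60, t_ref = NULL) {
  validate_rule(rule)
  bind <- data.frame(row.names = "1") # 1 row, 0 cols: the empty binding
  for (atom in order_atoms(rule$antecedent)) {
    if (nrow(bind) == 0) break
    bind <- switch(atom$kind,
      class = {
        mem <- class_members(kb, atom$class_name, window, t_ref)
        bind_join_values(bind, atom$var, mem)
      },
      property = {
        pairs <- property_pairs(kb, atom$property, window, t_ref)
        bind_join_pairs(bind, atom$subject, atom$object, pairs)
      },
      comparison = {
        if (!atom$var %in% names(bind))
          vw_stop("comparison on unbound variable %s", atom$var)
        vals <- value_of_individuals(kb, bind[[atom$var]])
        keep <- compare_op(vals, atom$op, atom$const)
        keep[is.na(keep)] <- FALSE
        bind[keep, , drop = FALSE]
      })
  }
  rownames(bind) <- NULL
  bind
}

# Greedy join-order selection: conjunction semantics are order-free, so
# atoms are evaluated filters-first to keep intermediate binding tables
# small (an unbound class atom before its property atom would otherwise
# cross-join the whole individual universe). Deterministic: within a
# priority tier the original antecedent order is kept.
order_atoms <- function(atoms) {
  done <- rep(FALSE, length(atoms))
  bound <- character()
  out <- list()
  while (!all(done)) {
    pick <- 0L
    for (tier in 1:4) {
      for (i in seq_along(atoms)) {
        if (done[i]) next
        vs <- atom_vars(atoms[[i]])
        ok <- switch(tier,
          all(vs %in% bound),
          atoms[[i]]$kind == "property" && any(vs %in% bound),
          atoms[[i]]$kind == "class",
          TRUE)
        if (ok) {
          pick <- i
          break
        }
      }
      if (pick > 0) break
    }
    done[pick] <- TRUE
    bound <- union(bound, atom_vars(atoms[[pick]]))
    out[[length(out) + 1]] <- atoms[[pick]]
  }
  out
}

bind_join_values <- function(bind, var, values) {
  values <- unique(values)
  if (var %in% names(bind)) {
    return(bind[bind[[var]] %in% values, , drop = FALSE])
  }
  if (length(values) == 0) return(bind[0, , drop = FALSE])
  out <- bind[rep(seq_len(nrow(bind)), times = length(values)), , drop = FALSE]
  out[[var]] <- rep(values, each = nrow(bind))
  out
}

bind_join_pairs <- function(bind, subj, obj, pairs) {
  sv <- is_var(subj); ov <- is_var(obj)
  if (!sv) pairs <- pairs[pairs$subject == subj, , drop = FALSE]
  if (!ov) pairs <- pairs[pairs$object == obj, , drop = FALSE]
  cols <- list()
  if (sv && ov && subj == obj) {
    keep <- pairs$subject == pairs$object
    cols[[subj]] <- pairs$subject[keep]
  } else {
    if (sv) cols[[subj]] <- pairs$subject
    if (ov) cols[[obj]] <- pairs$object
  }
  if (length(cols) == 0) {
    # both arguments constant: the atom is a plain filter
    return(if (nrow(pairs) > 0) bind else bind[0, , drop = FALSE])
  }
  cand <- unique(as.data.frame(cols, check.names = FALSE,
                               stringsAsFactors = FALSE,
                               optional = TRUE))
  common <- intersect(names(bind), names(cand))
  if (length(common) == 0) {
    if (nrow(cand) == 0) return(bind[0, , drop = FALSE])
    out <- bind[rep(seq_len(nrow(bind)), times = nrow(cand)), , drop = FALSE]
    for (cn in names(cand)) out[[cn]] <- rep(cand[[cn]], each = nrow(bind))
    rownames(out) <- NULL
    return(out)
  }
  merge(bind, cand, by = common)
}

# ---- alert construction ----------------------------------------------------

alert_from_binding <- function(kb, rule, binding) {
  vals <- unlist(binding, use.names = FALSE)
  pats <- unique(ind_strip(vals[startsWith(vals, IND_PAT)], IND_PAT))
  ev <- ind_strip(vals[startsWith(vals, IND_OBS)], IND_OBS)
  ev <- c(ev, ind_strip(vals[startsWith(vals, IND_RES)], IND_RES))
  ev <- sort(unique(ev))
  if (length(ev) == 0) return(NULL)
  m <- match(ev, kb$observations$observation_id)
  if (length(pats) == 0)
    pats <- unique(kb$observations$patient_id[m])
  ts <- max(kb$observations$timestamp[m])
  label <- rule$consequent$label
  data.frame(
    alert_id = paste0("al:", pats[1], "|", label, "|",
                      paste(ev, collapse = ",")),
    patient_id = pats[1], timestamp = ts, label = label,
    rule_id = rule$rule_id,
    evidence = I(list(ev)), stringsAsFactors = FALSE)
}

#' Apply rules by forward chaining to a fixpoint
#'
#' Repeatedly matches every enabled rule; `assert_class` consequents add
#' derived class assertions, `emit_alert` consequents append deduplicated
#' alerts (one per distinct patient/label/evidence) to the alert log.
#' Rules introduce no new individuals, so iteration terminates, and the
#' result is independent of rule ordering.
#'
#' @param kb knowledge base.
#' @param rules list of rules; default: all enabled rules stored in the KB.
#' @param window co-occurrence window in seconds (see [match_rule()]).
#' @param t_ref optional evaluation instant.
#' @return list with elements `kb` (updated) and `alerts` (data.frame of
#'   newly emitted alerts).
#' @export
apply_all <- function(kb, rules = NULL, window = 60, t_ref = NULL) {
  if (is.null(rules)) rules <- kb$rules
  rules <- Filter(function(r) isTRUE(r$enabled), rules)
  for (r in rules) validate_rule(r)
  new_alerts <- empty_alerts()
  repeat {
    changed <- FALSE
    for (rule in rules) {
      bind <- match_rule(kb, rule, window = window, t_ref = t_ref)
      if (nrow(bind) == 0) next
      if (rule$consequent$type == "assert_class") {
        inds <- unique(bind[[rule$consequent$var]])
        have <- kb$derived$individual[
          kb$derived$class_name == rule$consequent$class_name]
        add <- setdiff(inds, have)
        if (length(add)) {
          kb$derived <- rbind(kb$derived, data.frame(
            class_name = rule$consequent$class_name, individual = add,
            stringsAsFactors = FALSE))
          changed <- TRUE
        }
      } else {
        for (i in seq_len(nrow(bind))) {
          al <- alert_from_binding(kb, rule, bind[i, , drop = FALSE])
          if (is.null(al)) next
          if (!al$alert_id %in% new_alerts$alert_id &&
              !al$alert_id %in% kb$alerts$alert_id) {
            new_alerts <- rbind(new_alerts, al)
          }
        }
      }
    }
    if (!changed) break
  }
  kb <- kb_append_alerts(kb, new_alerts)
  list(kb = kb, alerts = new_alerts)
}

#' Query derived class assertions
#' @param kb knowledge base.
#' @param class_name e.g. `"AbnormalVitalSign"`.
#' @return character vector of individuals.
#' @export
kb_derived <- function(kb, class_name) {
  kb$derived$individual[kb$derived$class_name == class_name]
}

# ---- alert JSONL -----------------------------------------------------------

#' Write / read alerts as JSON lines
#'
#' One JSON object per line with ISO-8601 timestamps.
#' @param alerts alert data.frame (as in `kb$alerts`).
#' @param path file path.
#' @param append append to an existing file?
#' @return `write_alerts_jsonl`: invisibly, the path. `read_alerts_jsonl`:
#'   alert data.frame.
#' @export
write_alerts_jsonl <- function(alerts, path, append = FALSE) {
  lines <- vapply(seq_len(nrow(alerts)), function(i) {
    jsonlite::toJSON(list(
      alert_id = alerts$alert_id[i], patient_id = alerts$patient_id[i],
      timestamp = format_instant(alerts$timestamp[i]),
      label = alerts$label[i], rule_id = alerts$rule_id[i],
      evidence = alerts$evidence[[i]]),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' @rdname write_alerts_jsonl
#' @export
read_alerts_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alerts())
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    data.frame(alert_id = x$alert_id, patient_id = x$patient_id,
               timestamp = parse_instant(x$timestamp), label = x$label,
               rule_id = x$rule_id,
               evidence = I(list(as.character(x$evidence))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
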