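# Independent brute-force oracles used by the property tests. These
# deliberately re-derive everything from raw KB tables with naive code:
# they must stay independent of the implementation paths they check.

# -- interval membership by direct per-interval scan -------------------------
oracle_in_region <- function(region, x) {
  for (i in seq_len(nrow(region))) {
    lo_ok <- if (region$lower_closed[i]) x >= region$lower[i] else
      x > region$lower[i]
    hi_ok <- if (region$upper_closed[i]) x <= region$upper[i] else
      x < region$upper[i]
    if (lo_ok && hi_ok) return(TRUE)
  }
  FALSE
}

oracle_classify <- function(kb, sign_code, x) {
  for (ax in kb$axioms) {
    if (ax$sign_code == sign_code && oracle_in_region(ax$region, x))
      return(TRUE)
  }
  FALSE
}

# -- exhaustive rule-binding enumeration -------------------------------------
oracle_universe <- function(kb) {
  obs <- kb$observations
  unique(c(paste0("pat:", names(kb$patients)),
           if (nrow(obs)) paste0("vs:", obs$patient_id, ":", obs$sign_code),
           if (nrow(obs)) paste0("obs:", obs$observation_id),
           if (nrow(obs)) paste0("res:", obs$observation_id)))
}

oracle_obs_row <- function(kb, id) {
  kb$observations[kb$observations$observation_id == id, , drop = FALSE]
}

oracle_latest_pairs <- function(kb, window) {
  obs <- kb$observations
  pairs <- character()
  for (pat in unique(obs$patient_id)) {
    po <- obs[obs$patient_id == pat, , drop = FALSE]
    t_ref <- max(as.numeric(po$timestamp))
    for (s in unique(po$sign_code)) {
      ss <- po[po$sign_code == s, , drop = FALSE]
      best <- ss[which.max(as.numeric(ss$timestamp)), ]
      if (t_ref - as.numeric(best$timestamp) <= window) {
        pairs <- c(pairs, paste0("pat:", pat, "->obs:", best$observation_id))
      }
    }
  }
  pairs
}

oracle_class_holds <- function(kb, class_name, ind) {
  obs <- kb$observations
  if (class_name == "Patient")
    return(ind %in% paste0("pat:", names(kb$patients)))
  if (class_name == "VitalSign")
    return(nrow(obs) > 0 &&
             ind %in% paste0("vs:", obs$patient_id, ":", obs$sign_code))
  if (class_name == "Observation")
    return(ind %in% paste0("obs:", obs$observation_id))
  if (class_name == "Result")
    return(ind %in% paste0("res:", obs$observation_id))
  if (class_name == "AbnormalRange") {
    if (!startsWith(ind, "res:")) return(FALSE)
    row <- oracle_obs_row(kb, sub("^res:", "", ind))
    if (nrow(row) == 0 || is.na(row$value)) return(FALSE)
    return(oracle_classify(kb, row$sign_code, row$value))
  }
  ax <- kb$axioms[[class_name]]
  if (!is.null(ax)) {
    if (!startsWith(ind, "res:")) return(FALSE)
    row <- oracle_obs_row(kb, sub("^res:", "", ind))
    if (nrow(row) == 0 || row$sign_code != ax$sign_code || is.na(row$value))
      return(FALSE)
    return(oracle_in_region(ax$region, row$value))
  }
  ind %in% kb$derived$individual[kb$derived$class_name == class_name]
}

oracle_property_holds <- function(kb, property, s, o, window) {
  obs <- kb$observations
  if (property == "VitalSignhasObservation") {
    if (!startsWith(s, "vs:") || !startsWith(o, "obs:")) return(FALSE)
    row <- oracle_obs_row(kb, sub("^obs:", "", o))
    return(nrow(row) == 1 &&
             s == paste0("vs:", row$patient_id, ":", row$sign_code))
  }
  if (property == "hasResult")
    return(startsWith(s, "obs:") && o == sub("^obs:", "res:", s))
  if (property == "observedProperty") {
    if (!startsWith(s, "obs:")) return(FALSE)
    row <- oracle_obs_row(kb, sub("^obs:", "", s))
    return(nrow(row) == 1 && row$sign_code == o)
  }
  if (property == "latestObservation")
    return(paste0(s, "->", o) %in% oracle_latest_pairs(kb, window))
  stop("oracle: unknown property ", property)
}

oracle_value_of <- function(kb, ind) {
  id <- sub("^(res|obs):", "", ind)
  row <- oracle_obs_row(kb, id)
  if (nrow(row) == 0 || (!startsWith(ind, "res:") && !startsWith(ind, "obs:")))
    return(NA_real_)
  row$value
}

oracle_match <- function(kb, rule, window = 60) {
  vars <- unique(unlist(lapply(rule$antecedent, function(a) {
    switch(a$kind,
      class = a$var,
      property = Filter(function(x) startsWith(x, "?"),
                        c(a$subject, a$object)),
      comparison = a$var)
  })))
  inds <- oracle_universe(kb)
  if (length(inds) == 0)
    return(stats::setNames(data.frame(matrix(character(), 0, length(vars))),
                           vars))
  grid <- expand.grid(rep(list(inds), length(vars)), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vars
  # every assignment is checked against every atom; repeated
  # (individual, atom) checks are deduplicated for speed only -- the naive
  # per-individual predicates above stay the single source of truth
  keep <- rep(TRUE, nrow(grid))
  for (a in rule$antecedent) {
    keep <- keep & switch(a$kind,
      class = {
        ok_ind <- vapply(inds, function(i)
          oracle_class_holds(kb, a$class_name, i), logical(1))
        unname(ok_ind[match(grid[[a$var]], inds)])
      },
      property = {
        svals <- if (startsWith(a$subject, "?")) grid[[a$subject]] else
          rep(a$subject, nrow(grid))
        ovals <- if (startsWith(a$object, "?")) grid[[a$object]] else
          rep(a$object, nrow(grid))
        key <- paste0(svals, "\r", ovals)
        uk <- unique(cbind(svals, ovals))
        hold <- vapply(seq_len(nrow(uk)), function(i)
          oracle_property_holds(kb, a$property, uk[i, 1], uk[i, 2], window),
          logical(1))
        hold[match(key, paste0(uk[, 1], "\r", uk[, 2]))]
      },
      comparison = {
        uv <- unique(grid[[a$var]])
        vals <- vapply(uv, function(i) oracle_value_of(kb, i), numeric(1))
        v <- vals[match(grid[[a$var]], uv)]
        ok <- switch(a$op, "<" = v < a$const, "<=" = v <= a$const,
                     ">" = v > a$const, ">=" = v >= a$const,
                     "=" = v == a$const)
        ok & !is.na(ok)
      })
  }
  grid[keep, , drop = FALSE]
}

bindings_canon <- function(df, vars) {
  if (nrow(df) == 0) {
    out <- stats::setNames(as.data.frame(rep(list(character()), length(vars))),
                           vars)
    return(out)
  }
  for (v in setdiff(vars, names(df))) df[[v]] <- NA_character_
  df <- df[vars]
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# -- exhaustive best-split search (information gain) -------------------------
oracle_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_best_gain <- function(df, label_col = "label") {
  feats <- setdiff(names(df), label_col)
  feats <- feats[!startsWith(feats, ".")]
  h <- oracle_entropy(df[[label_col]])
  best <- 0
  for (f in feats) {
    x <- df[[f]]
    if (!is.numeric(x)) next
    vals <- sort(unique(x))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      left <- df[[label_col]][x < thr]
      right <- df[[label_col]][x >= thr]
      gain <- h - (length(left) * oracle_entropy(left) +
                     length(right) * oracle_entropy(right)) / nrow(df)
      if (gain > best) best <- gain
    }
  }
  best
}

# -- independent recursive tree tracer ---------------------------------------
oracle_trace <- function(node, row) {
  if (node$type == "leaf") return(node$label)
  v <- row[[node$attr]]
  if (node$kind == "real") {
    child <- if (is.na(v)) {
      if (node$children$left$support >= node$children$right$support)
        node$children$left else node$children$right
    } else if (v < node$threshold) node$children$left else node$children$right
  } else {
    v <- as.character(v)
    child <- if (!is.na(v) && v %in% names(node$children)) {
      node$children[[v]]
    } else {
      sup <- vapply(node$children, function(ch) ch$support, numeric(1))
      node$children[[which.max(sup)]]
    }
  }
  oracle_trace(child, row)
}

# -- small random fixtures ---------------------------------------------------
random_small_kb <- function(seed, n_obs = NULL, n_axioms = 2) {
  set.seed(seed)
  if (is.null(n_obs)) n_obs <- sample(0:8, 1)
  signs <- c("Perf", "Temp", "NBP_Sys")
  kb <- kb_new()
  pats <- c("pA", "pB")
  for (p in pats) kb <- kb_add_patient(kb, p)
  for (k in seq_len(n_axioms)) {
    s <- sample(signs, 1)
    lo <- round(stats::runif(1, -5, 5), 2)
    hi <- lo + round(stats::runif(1, 0.5, 5), 2)
    region <- if (stats::runif(1) < 0.5) interval_set(-Inf, hi) else
      interval_set(lo, hi, sample(c(TRUE, FALSE), 1), sample(c(TRUE, FALSE), 1))
    ax <- abnormal_range_axiom(paste0(s, "AN"), s, region, "manual")
    kb <- upsert_abnormal_range(kb, ax)
  }
  t0 <- as.numeric(parse_instant("2024-01-01T00:00:00Z"))
  if (n_obs > 0) {
    df <- data.frame(
      observation_id = paste0("o", seq_len(n_obs)),
      patient_id = sample(pats, n_obs, replace = TRUE),
      sensor_id = NA_character_,
      sign_code = sample(signs, n_obs, replace = TRUE),
      timestamp = t0 + sort(sample(0:120, n_obs)),
      value = round(stats::runif(n_obs, -5, 10), 2),
      stringsAsFactors = FALSE)
    kb <- assert_observations(kb, df)
  }
  kb
}

printed_alarm_conditions <- function() {
  list(c("Perf", "<", "0.5"), c("AWV", "<", "3749.05"),
       c("AWF", "<", "10.4"), c("NBP_Sys", "<", "105"))
}

eval_models <- function() {
  default_signal_models()[c("SpO2", "Perf", "AWV", "AWF", "NBP_Sys")]
}
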