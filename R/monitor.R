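# Time-sweep monitoring of an observation stream.
#
# apply_all() evaluates rules at a single instant (each patient's latest
# state). monitor_stream() replays the stored observations in time order so
# that alarm rules are evaluated at every measurement instant, emitting one
# alert per entry into the alarm state (a contiguous run of satisfied
# conditions yields a single alert). Emergency-form rules (the shape built
# by emergency_rule_from_conditions) are evaluated on a vectorized
# last-value-carried-forward grid; other rules fall back to apply_all at
# the end state.

#' Monitor the knowledge base's observation stream
#'
#' @param kb knowledge base whose observations to sweep.
#' @param rules rules to evaluate; default: all enabled KB rules.
#' @param window co-occurrence window in seconds: a sign's last measurement
#'   older than this at the evaluation instant is considered stale and the
#'   condition cannot hold.
#' @return list with `kb` (alerts appended, derived facts updated) and
#'   `alerts` (data.frame of newly emitted alerts).
#' @export
monitor_stream <- function(kb, rules = NULL, window = 60) {
  if (is.null(rules)) rules <- kb$rules
  rules <- Filter(function(r) isTRUE(r$enabled), rules)
  fast <- list(); slow <- list()
  for (r in rules) {
    cond <- decode_emergency_conditions(r)
    if (!is.null(cond)) fast[[r$rule_id]] <- list(rule = r, cond = cond)
    else slow[[r$rule_id]] <- r
  }
  alerts <- empty_alerts()
  for (f in fast) {
    a <- sweep_emergency_rule(kb, f$rule, f$cond, window)
    if (nrow(a)) alerts <- rbind(alerts, a)
  }
  if (nrow(alerts)) {
    alerts <- alerts[!duplicated(alerts$alert_id), , drop = FALSE]
    alerts <- alerts[!alerts$alert_id %in% kb$alerts$alert_id, , drop = FALSE]
  }
  kb <- kb_append_alerts(kb, alerts)
  if (length(slow)) {
    res <- apply_all(kb, slow, window = window)
    kb <- res$kb
    if (nrow(res$alerts)) alerts <- rbind(alerts, res$alerts)
  }
  list(kb = kb, alerts = alerts)
}

sweep_emergency_rule <- function(kb, rule, cond, window) {
  out <- list()
  signs <- unique(cond$sign_code)
  obs <- kb$observations[kb$observations$sign_code %in% signs, , drop = FALSE]
  for (pat in unique(obs$patient_id)) {
    po <- obs[obs$patient_id == pat, , drop = FALSE]
    if (!all(signs %in% po$sign_code)) next
    po <- po[order(po$timestamp, po$observation_id), , drop = FALSE]
    grid <- sort(unique(as.numeric(po$timestamp)))
    n <- length(grid)
    # last-value-carried-forward per sign onto the common grid
    val <- list(); oid <- list(); ots <- list()
    for (s in signs) {
      so <- po[po$sign_code == s, , drop = FALSE]
      pos <- findInterval(grid, as.numeric(so$timestamp))
      val[[s]] <- ifelse(pos >= 1, so$value[pmax(pos, 1)], NA_real_)
      oid[[s]] <- ifelse(pos >= 1, so$observation_id[pmax(pos, 1)],
                         NA_character_)
      ots[[s]] <- ifelse(pos >= 1, as.numeric(so$timestamp)[pmax(pos, 1)],
                         NA_real_)
    }
    state <- rep(TRUE, n)
    for (i in seq_len(nrow(cond))) {
      s <- cond$sign_code[i]
      fresh <- !is.na(ots[[s]]) & (grid - ots[[s]]) <= window
      ok <- compare_op(val[[s]], cond$op[i], cond$value[i])
      ok[is.na(ok)] <- FALSE
      state <- state & fresh & ok
    }
    edge <- state & !c(FALSE, state[-n])
    for (k in which(edge)) {
      ev <- sort(unique(stats::na.omit(
        vapply(signs, function(s) oid[[s]][k], character(1)))))
      out[[length(out) + 1]] <- data.frame(
        alert_id = paste0("al:", pat, "|", rule$consequent$label, "|",
                          paste(ev, collapse = ",")),
        patient_id = pat,
        timestamp = as.POSIXct(grid[k], origin = "1970-01-01", tz = "UTC"),
        label = rule$consequent$label, rule_id = rule$rule_id,
        evidence = I(list(ev)), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_alerts())
  do.call(rbind, out)
}
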