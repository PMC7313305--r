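# Information life-cycle preparation: outlier/missing flagging on raw
# records, reversible attribute selection, type/format transformation, and
# construction of alarm-labelled training instances for the tree learner.

#' Flag outliers and missing values in a raw record table
#'
#' @param table long-format data.frame with columns `patient_id`,
#'   `timestamp`, `attribute`, `value` (raw text).
#' @param catalog named list of [vital_sign()] definitions supplying the
#'   plausible ranges; attributes without metadata are tagged `unknown`
#'   with a warning.
#' @return list with `table` (input plus a `status` column in
#'   `ok/missing/outlier/unknown`) and `flags` (data.frame of row
#'   coordinates for every non-`ok` cell). No rows are dropped.
#' @export
flag_outliers_and_missing <- function(table, catalog = default_sign_catalog()) {
  stopifnot(all(c("patient_id", "timestamp", "attribute", "value") %in%
                  names(table)))
  val <- as.character(table$value)
  status <- rep("ok", nrow(table))
  missing <- is.na(val) | !nzchar(trimws(val)) | trimws(val) %in% c("?", "NA")
  status[missing] <- "missing"
  known <- table$attribute %in% names(catalog)
  if (any(!known)) {
    vw_warn("no metadata for attribute(s): %s",
            paste(unique(table$attribute[!known]), collapse = ", "))
    status[!known & !missing] <- "unknown"
  }
  for (code in intersect(unique(table$attribute), names(catalog))) {
    d <- catalog[[code]]
    if (d$value_kind != "real") next
    sel <- which(table$attribute == code & status == "ok")
    num <- suppressWarnings(as.numeric(parse_numeric_text(val[sel])))
    out <- (!is.na(d$plausible_lower) & num < d$plausible_lower) |
      (!is.na(d$plausible_upper) & num > d$plausible_upper)
    out[is.na(out)] <- FALSE
    status[sel[out]] <- "outlier"
  }
  table$status <- status
  flagged <- which(status != "ok")
  flags <- data.frame(row = flagged,
                      patient_id = table$patient_id[flagged],
                      attribute = table$attribute[flagged],
                      status = status[flagged], stringsAsFactors = FALSE)
  list(table = table, flags = flags)
}

#' Reversible attribute selection
#'
#' Keeps only the selected columns of a wide table; the returned stash
#' allows lossless restoration with [restore_attributes()]. Selected names
#' absent from the table are ignored with a warning.
#'
#' @param table wide data.frame.
#' @param selection non-empty character vector of column names to keep.
#' @return list with `table` (reduced) and `stash`.
#' @export
select_attributes <- function(table, selection) {
  if (length(selection) == 0) vw_stop("selection must be non-empty")
  absent <- setdiff(selection, names(table))
  if (length(absent) == length(selection))
    vw_stop("selection shares no columns with the table")
  if (length(absent))
    vw_warn("selected attribute(s) not present: %s",
            paste(absent, collapse = ", "))
  keep <- intersect(names(table), selection)
  stash <- list(removed = table[setdiff(names(table), keep)],
                order = names(table), absent = absent)
  list(table = table[keep], stash = stash)
}

#' @rdname select_attributes
#' @param stash the stash returned by `select_attributes`.
#' @return the original table, column order included.
#' @export
restore_attributes <- function(table, stash) {
  full <- cbind(table, stash$removed)
  full[stash$order]
}

# numeric text with thousands separators ("3,749.05" == "3749.05")
parse_numeric_text <- function(x) {
  x <- trimws(as.character(x))
  grouped <- grepl("^-?[0-9]{1,3}(,[0-9]{3})+(\\.[0-9]+)?$", x)
  x[grouped] <- gsub(",", "", x[grouped], fixed = TRUE)
  x
}

#' Transform a raw wide table into typed columns
#'
#' Numeric-looking text columns (locale thousands separators accepted)
#' become doubles; timestamp-like columns are unified to canonical
#' ISO-8601 UTC; remaining text columns become nominal factors.
#' Untransformable cells become missing values and are reported in the
#' `flags` attribute of the result; nothing is raised. The operation is
#' idempotent.
#'
#' @param table wide data.frame.
#' @return typed data.frame with a `flags` attribute (data.frame of
#'   row/column coordinates of failed conversions).
#' @export
transform_table <- function(table) {
  flags <- list()
  for (cn in names(table)) {
    col <- table[[cn]]
    if (is.numeric(col) || is.factor(col) || inherits(col, "POSIXct")) next
    chr <- trimws(as.character(col))
    chr[!nzchar(chr)] <- NA
    present <- !is.na(chr)
    if (!any(present)) next
    num <- suppressWarnings(as.numeric(parse_numeric_text(chr)))
    if (all(!is.na(num[present]))) {
      table[[cn]] <- num
      next
    }
    ts <- parse_instant(chr)
    if (sum(!is.na(ts[present])) / sum(present) >= 0.5 &&
        !all(grepl("^[A-Za-z]+$", chr[present]))) {
      fail <- present & is.na(ts)
      if (any(fail)) flags[[length(flags) + 1]] <-
          data.frame(row = which(fail), column = cn, stringsAsFactors = FALSE)
      table[[cn]] <- format_instant(ts)
      table[[cn]][is.na(ts)] <- NA
      next
    }
    table[[cn]] <- factor(chr)
  }
  attr(table, "flags") <- if (length(flags)) do.call(rbind, flags) else
    data.frame(row = integer(), column = character())
  table
}

#' Build an alarm-labelled training table from the knowledge base
#'
#' One positive instance per logged alert: the features are the latest
#' value of each real-valued catalog sign observed for the alert's patient
#' within `window` seconds before (and including) the alert instant.
#' Negative `NORMAL` instances are sampled from alert-free periods at
#' `neg_ratio` negatives per positive (times at least `window` s before and
#' `neg_exclusion` s after any alert of the same patient). Deterministic
#' given the KB and seed.
#'
#' @param kb knowledge base with alert history.
#' @param window feature look-back window, seconds.
#' @param neg_ratio negatives sampled per positive.
#' @param neg_exclusion seconds after an alert still considered
#'   alarm-contaminated when sampling negatives (covers episode tails).
#' @param seed integer seed for negative sampling.
#' @return a labelled instance table: one numeric column per real sign,
#'   `label`, and provenance columns `.patient`, `.time`.
#' @export
build_training_set <- function(kb, window = 60, neg_ratio = 1,
                               neg_exclusion = 300, seed = 1) {
  feats <- names(kb$signs)[vapply(kb$signs, `[[`, "", "value_kind") == "real"]
  obs <- kb$observations
  features_at <- function(pat, t) {
    sel <- obs$patient_id == pat &
      as.numeric(obs$timestamp) > as.numeric(t) - window &
      obs$timestamp <= t
    po <- obs[sel, , drop = FALSE]
    vapply(feats, function(s) {
      ss <- po[po$sign_code == s, , drop = FALSE]
      if (nrow(ss) == 0) NA_real_ else ss$value[which.max(ss$timestamp)]
    }, numeric(1))
  }
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(kb$alerts))) {
    fv <- features_at(kb$alerts$patient_id[i], kb$alerts$timestamp[i])
    if (all(is.na(fv))) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      t(fv), label = kb$alerts$label[i],
      .patient = kb$alerts$patient_id[i],
      .time = kb$alerts$timestamp[i],
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    vw_warn("%d alert(s) had no observations in the window and were dropped",
            dropped)
  n_pos <- length(rows)
  n_neg <- round(neg_ratio * n_pos)
  if (n_neg > 0) {
    cands <- list()
    for (pat in unique(obs$patient_id)) {
      ts <- sort(unique(as.numeric(obs$timestamp[obs$patient_id == pat])))
      a_ts <- as.numeric(kb$alerts$timestamp[kb$alerts$patient_id == pat])
      ok <- rep(TRUE, length(ts))
      for (at in a_ts) ok <- ok & !(ts >= at - window & ts <= at + neg_exclusion)
      if (any(ok)) cands[[pat]] <- data.frame(pat = pat, t = ts[ok])
    }
    cands <- do.call(rbind, cands)
    if (!is.null(cands) && nrow(cands) > 0) {
      take <- with_seed(seed, sample(nrow(cands), min(n_neg, nrow(cands))))
      if (length(take) < n_neg)
        vw_warn("only %d alert-free candidate times for %d requested negatives",
                nrow(cands), n_neg)
      for (j in sort(take)) {
        t <- as.POSIXct(cands$t[j], origin = "1970-01-01", tz = "UTC")
        fv <- features_at(cands$pat[j], t)
        rows[[length(rows) + 1]] <- data.frame(
          t(fv), label = "NORMAL", .patient = cands$pat[j], .time = t,
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric()), length(feats)),
                                         feats))
    out$label <- character()
    out$.patient <- character()
    out$.time <- as.POSIXct(character(), tz = "UTC")
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window") <- window
  out
}

#' Export a labelled instance table to ARFF
#'
#' Writes the feature and label columns (provenance columns are dropped)
#' through `foreign::write.arff` for interoperability with WEKA-style
#' tooling.
#'
#' @param table labelled instance table.
#' @param path output `.arff` path.
#' @return invisibly, the path.
#' @export
write_instances_arff <- function(table, path) {
  df <- table[!startsWith(names(table), ".")]
  df$label <- factor(df$label)
  foreign::write.arff(df, path)
  invisible(path)
}
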