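# Seeded generator of multi-patient vital-sign streams with planted
# conjunctive emergency episodes. Values are Gaussian around a baseline
# (optional linear drift); during an episode every predicate sign is driven
# to satisfy its condition with margin m, and outside episodes predicate
# signs stay on the normal side of every threshold by at least m (except
# injected outliers). The generator trades physiological realism for exact
# ground truth: it exercises the reasoning loop, not physiology.

#' Signal model for one vital sign
#'
#' @param sign_code catalog code.
#' @param mean,sd baseline Gaussian parameters (sign units; `sd >= 0`).
#' @param period sampling period in seconds (> 0).
#' @param drift mean drift per hour (sign units).
#' @param missing_rate,outlier_rate per-sample injection rates in `[0, 1)`.
#' @return a `vw_signal_model` list.
#' @export
signal_model <- function(sign_code, mean, sd, period = 60, drift = 0,
                         missing_rate = 0, outlier_rate = 0) {
  stopifnot(sd >= 0, period > 0,
            missing_rate >= 0, missing_rate < 1,
            outlier_rate >= 0, outlier_rate < 1)
  structure(list(sign_code = sign_code, mean = mean, sd = sd, period = period,
                 drift = drift, missing_rate = missing_rate,
                 outlier_rate = outlier_rate),
            class = "vw_signal_model")
}

#' Default signal models for the monitored channels
#'
#' Baselines are invented fixture values on plausible adult scales; they
#' are simulator settings, not clinical reference ranges.
#'
#' @return named list of [signal_model()] objects.
#' @export
default_signal_models <- function() {
  ms <- list(
    signal_model("SpO2",    97,   1),
    signal_model("Perf",    2.0,  0.4),
    signal_model("AWV",     5000, 400),
    signal_model("AWF",     15,   1.5),
    signal_model("NBP_Sys", 120,  8),
    signal_model("Temp",    36.8, 0.3),
    signal_model("Pulse",   72,   8)
  )
  stats::setNames(ms, vapply(ms, `[[`, "", "sign_code"))
}

#' Planted conjunctive emergency
#'
#' @param label alarm label, e.g. `"SpO2 LOW PERF"`.
#' @param conditions as in [emergency_rule_from_conditions()].
#' @param episode_rate expected episodes per patient-day (Poisson).
#' @param episode_duration episode length, seconds.
#' @param margin separation `m` (> 0, sign units) kept between generated
#'   values and every planted threshold.
#' @return a `vw_planted` list.
#' @export
planted_emergency <- function(label, conditions, episode_rate = 2,
                              episode_duration = 120, margin = 0.2) {
  stopifnot(margin > 0, episode_duration > 0, episode_rate >= 0)
  structure(list(label = label, conditions = normalize_conditions(conditions),
                 episode_rate = episode_rate,
                 episode_duration = episode_duration, margin = margin),
            class = "vw_planted")
}

# per-sign regions: where values must lie inside an episode ("satisfy the
# predicate with margin") and outside one ("fail it with margin"); errors
# if the predicate is unsatisfiable under the margin
planted_regions <- function(planted) {
  m <- planted$margin
  cond <- planted$conditions
  regions <- list()
  for (s in unique(cond$sign_code)) {
    ep_lo <- -Inf; ep_hi <- Inf
    base_lo <- -Inf; base_hi <- Inf
    sub <- cond[cond$sign_code == s, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      c0 <- sub$value[i]
      if (sub$op[i] %in% c("<", "<=")) {
        ep_hi <- min(ep_hi, c0 - m)
        base_lo <- max(base_lo, c0 + m)
      } else {
        ep_lo <- max(ep_lo, c0 + m)
        base_hi <- min(base_hi, c0 - m)
      }
    }
    if (ep_lo > ep_hi)
      vw_stop("planted predicate for '%s' unsatisfiable with margin %g on sign %s",
              planted$label, m, s)
    if (base_lo > base_hi)
      vw_stop("baseline region for '%s' empty with margin %g on sign %s",
              planted$label, m, s)
    regions[[s]] <- list(ep_lo = ep_lo, ep_hi = ep_hi,
                         base_lo = base_lo, base_hi = base_hi, margin = m)
  }
  regions
}

# clamp baseline draws onto the allowed side(s) by reflection at the band
# edge, then hard clamping (keeps the margin guarantee)
project_into <- function(x, lo, hi) {
  if (is.finite(lo)) {
    below <- x < lo
    x[below] <- lo + (lo - x[below])
  }
  if (is.finite(hi)) {
    above <- x > hi
    x[above] <- hi - (x[above] - hi)
  }
  pmin(pmax(x, if (is.finite(lo)) lo else -Inf),
       if (is.finite(hi)) hi else Inf)
}

# normal-side draws for the training fixture: half projected baseline
# Gaussian, half uniform in the edge band adjacent to the margin, so that
# data hugs both edges of the empty margin interval and midpoint split
# thresholds land inside it
fixture_normal_draw <- function(n, reg, mod) {
  base <- project_into(stats::rnorm(n, mod$mean, mod$sd),
                       reg$base_lo, reg$base_hi)
  edge <- if (is.finite(reg$base_lo)) {
    stats::runif(n, reg$base_lo, min(reg$base_lo + reg$margin, reg$base_hi))
  } else {
    stats::runif(n, max(reg$base_hi - reg$margin, reg$base_lo), reg$base_hi)
  }
  ifelse(stats::runif(n) < 0.5, edge, base)
}

# episode draws: uniform in a band of width `margin` hugging the feasible
# bound (so learned midpoint thresholds land inside the margin band)
episode_draw <- function(n, reg) {
  if (is.finite(reg$ep_hi) && is.finite(reg$ep_lo)) {
    stats::runif(n, reg$ep_lo, reg$ep_hi)
  } else if (is.finite(reg$ep_hi)) {
    stats::runif(n, reg$ep_hi - reg$margin, reg$ep_hi)
  } else if (is.finite(reg$ep_lo)) {
    stats::runif(n, reg$ep_lo, reg$ep_lo + reg$margin)
  } else {
    vw_stop("episode region unbounded on both sides")
  }
}

#' Generate a synthetic observation stream with ground truth
#'
#' @param n_patients number of patients (ids `pat1`, `pat2`, ...).
#' @param models named list of [signal_model()] objects.
#' @param planted list of [planted_emergency()] objects; every predicate
#'   sign must have a model.
#' @param duration_hours stream length per patient.
#' @param seed integer seed; identical configuration and seed reproduce
#'   the output exactly.
#' @param start stream start instant.
#' @return list with `observations` (data.frame in the ingestion schema:
#'   `patient_id, sensor_id, sign_code, timestamp, value`, plus
#'   `observation_id`) and `annotations` (ground truth: `patient_id,
#'   label, start, end`, disjoint per patient and label).
#' @export
generate_stream <- function(n_patients = 3, models = default_signal_models(),
                            planted = list(), duration_hours = 24, seed = 1,
                            start = "2024-01-01T00:00:00Z") {
  stopifnot(n_patients >= 1, length(models) >= 1)
  if (inherits(planted, "vw_planted")) planted <- list(planted)
  regions <- lapply(planted, planted_regions)
  for (k in seq_along(planted)) {
    miss <- setdiff(unique(planted[[k]]$conditions$sign_code), names(models))
    if (length(miss))
      vw_stop("planted predicate sign(s) without a signal model: %s",
              paste(miss, collapse = ", "))
  }
  t0 <- as.numeric(parse_instant(start))
  dur <- duration_hours * 3600
  patients <- paste0("pat", seq_len(n_patients))
  catalog <- default_sign_catalog()

  obs <- list(); ann <- list()
  with_seed(seed, {
    for (pat in patients) {
      # schedule disjoint episodes per planted emergency
      episodes <- list()
      for (k in seq_along(planted)) {
        pl <- planted[[k]]
        n_ep <- stats::rpois(1, pl$episode_rate * duration_hours / 24)
        if (n_ep == 0 || dur <= pl$episode_duration) next
        starts <- sort(stats::runif(n_ep, 0, dur - pl$episode_duration))
        kept <- numeric()
        last_end <- -Inf
        for (st in starts) {
          if (st >= last_end + 300) { # >= 5 min apart keeps episodes distinct
            kept <- c(kept, st)
            last_end <- st + pl$episode_duration
          }
        }
        if (length(kept)) {
          episodes[[k]] <- cbind(kept, kept + pl$episode_duration)
          ann[[length(ann) + 1]] <- data.frame(
            patient_id = pat, label = pl$label,
            start = as.POSIXct(t0 + kept, origin = "1970-01-01", tz = "UTC"),
            end = as.POSIXct(t0 + kept + pl$episode_duration,
                             origin = "1970-01-01", tz = "UTC"),
            stringsAsFactors = FALSE)
        }
      }
      for (mi in seq_along(models)) {
        mod <- models[[mi]]
        s <- mod$sign_code
        tt <- if (dur < mod$period) numeric() else
          seq(0, dur - 1e-9, by = mod$period)
        n <- length(tt)
        if (n == 0) next
        mu <- mod$mean + mod$drift * tt / 3600
        x <- stats::rnorm(n, mu, mod$sd)
        in_ep <- rep(FALSE, n)
        for (k in seq_along(planted)) {
          reg <- regions[[k]][[s]]
          ep <- if (k <= length(episodes)) episodes[[k]] else NULL
          if (is.null(reg)) next
          # outside episodes stay on the normal side with margin
          x <- project_into(x, reg$base_lo, reg$base_hi)
          if (!is.null(ep)) {
            for (r in seq_len(nrow(ep))) {
              sel <- tt >= ep[r, 1] & tt < ep[r, 2]
              in_ep <- in_ep | sel
              if (any(sel)) x[sel] <- episode_draw(sum(sel), reg)
            }
          }
        }
        # injected anomalies (never inside an episode)
        if (mod$outlier_rate > 0) {
          hit <- stats::runif(n) < mod$outlier_rate & !in_ep
          if (any(hit)) {
            d <- catalog[[s]]
            hi <- if (!is.null(d) && !is.na(d$plausible_upper))
              d$plausible_upper else mod$mean + 10 * max(mod$sd, 1)
            x[hit] <- hi * 1.5 + abs(stats::rnorm(sum(hit), 0, max(mod$sd, 1)))
          }
        }
        if (mod$missing_rate > 0) {
          x[stats::runif(n) < mod$missing_rate & !in_ep] <- NA_real_
        }
        obs[[length(obs) + 1]] <- data.frame(
          observation_id = sprintf("%s-%s-%05d", pat, s, seq_len(n)),
          patient_id = pat,
          sensor_id = paste0(pat, "-", s, "-sensor"),
          sign_code = s,
          timestamp = as.POSIXct(t0 + tt, origin = "1970-01-01", tz = "UTC"),
          value = x, stringsAsFactors = FALSE)
      }
    }
  })
  observations <- if (length(obs)) do.call(rbind, obs) else
    data.frame(observation_id = character(), patient_id = character(),
               sensor_id = character(), sign_code = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               value = numeric(), stringsAsFactors = FALSE)
  observations <- observations[order(observations$timestamp,
                                     observations$patient_id,
                                     observations$sign_code), , drop = FALSE]
  rownames(observations) <- NULL
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(patient_id = character(), label = character(),
               start = as.POSIXct(character(), tz = "UTC"),
               end = as.POSIXct(character(), tz = "UTC"),
               stringsAsFactors = FALSE)
  rownames(annotations) <- NULL
  list(observations = observations, annotations = annotations)
}

#' Generate a balanced labelled training fixture
#'
#' Direct fixture for the tree learner: `n_per_class` rows per label. In
#' positive rows every predicate sign lies inside its episode band; in
#' negative (`NORMAL`) rows each predicate sign is independently placed in
#' the episode band with probability `partial_rate` (so that no single
#' feature threshold can separate a multi-condition predicate), but at
#' least one condition always fails by the margin. Labels are then flipped
#' with probability `noise_label_rate`.
#'
#' @param planted a [planted_emergency()].
#' @param n_per_class rows per class (>= 1).
#' @param noise_label_rate label-flip probability.
#' @param seed integer seed.
#' @param models named list of [signal_model()]; non-predicate signs are
#'   plain baseline draws.
#' @param partial_rate probability that a predicate sign of a negative row
#'   satisfies its own condition.
#' @return labelled instance table (features + `label`).
#' @export
generate_training_fixture <- function(planted, n_per_class = 1000,
                                      noise_label_rate = 0, seed = 1,
                                      models = default_signal_models(),
                                      partial_rate = 0.25) {
  stopifnot(n_per_class >= 1, noise_label_rate >= 0, noise_label_rate < 1)
  regions <- planted_regions(planted)
  pred_signs <- names(regions)
  feats <- vapply(models, `[[`, "", "sign_code")
  with_seed(seed, {
    n <- 2 * n_per_class
    df <- as.data.frame(lapply(models, function(mod)
      stats::rnorm(n, mod$mean, mod$sd)))
    names(df) <- feats
    pos <- seq_len(n_per_class)
    neg <- n_per_class + seq_len(n_per_class)
    for (s in pred_signs) {
      reg <- regions[[s]]
      df[[s]][pos] <- episode_draw(n_per_class, reg)
      in_band <- stats::runif(n_per_class) < partial_rate
      base <- fixture_normal_draw(n_per_class, reg, models[[s]])
      band <- episode_draw(n_per_class, reg)
      df[[s]][neg] <- ifelse(in_band, band, base)
    }
    if (length(pred_signs)) {
      # a negative row satisfying every condition gets one sign forced back
      all_sat <- rep(TRUE, n_per_class)
      for (s in pred_signs) {
        reg <- regions[[s]]
        v <- df[[s]][neg]
        all_sat <- all_sat & v >= reg$ep_lo - 1e-12 & v <= reg$ep_hi + 1e-12
      }
      if (any(all_sat)) {
        fix_sign <- pred_signs[1 + (which(all_sat) %% length(pred_signs))]
        for (s in unique(fix_sign)) {
          rows <- neg[which(all_sat)[fix_sign == s]]
          reg <- regions[[s]]
          df[[s]][rows] <- fixture_normal_draw(length(rows), reg,
                                               models[[s]])
        }
      }
    }
    df$label <- c(rep(planted$label, n_per_class), rep("NORMAL", n_per_class))
    flip <- stats::runif(n) < noise_label_rate
    df$label[flip] <- ifelse(df$label[flip] == "NORMAL", planted$label,
                             "NORMAL")
    attr(df, "n_flipped") <- sum(flip)
    df
  })
}

# ---- CSV I/O ---------------------------------------------------------------

#' Write / read observation and annotation tables as CSV
#'
#' The observation schema is
#' `patient_id,sensor_id,sign_code,timestamp,value` (plus
#' `observation_id`); timestamps are ISO-8601 UTC, missing values empty.
#'
#' @param df table to write.
#' @param path file path.
#' @return invisibly, the path (writers); a typed data.frame (readers).
#' @export
write_observations_csv <- function(df, path) {
  out <- df
  out$timestamp <- format_instant(out$timestamp)
  out$value <- ifelse(is.na(out$value), "", fmt_double(out$value))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("patient_id", "sensor_id", "sign_code", "timestamp", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    vw_stop("observation CSV lacks column(s): %s", paste(miss, collapse = ", "))
  df$timestamp <- parse_instant(df$timestamp)
  df$value <- suppressWarnings(as.numeric(parse_numeric_text(df$value)))
  df
}

#' @rdname write_observations_csv
#' @export
write_annotations_csv <- function(df, path) {
  out <- df
  out$start <- format_instant(out$start)
  out$end <- format_instant(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$start <- parse_instant(df$start)
  df$end <- parse_instant(df$end)
  df
}
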