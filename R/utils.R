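# shared helpers: seeded RNG scopes, canonical timestamps, misc

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before, so library internals never
#' perturb a caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Parse a timestamp into canonical UTC form
#'
#' Accepts ISO-8601 (`2020-05-31T12:00:00Z`), space-separated, date-only,
#' day-first slashed (`31/05/2020`) and English month-name forms, plus
#' numeric epoch seconds and POSIXct input. All results are POSIXct in UTC,
#' rounded to millisecond precision (the package's canonical resolution, so
#' serialization round-trips are exact).
#'
#' @param x character, numeric (epoch seconds) or POSIXct vector.
#' @return POSIXct vector (UTC); unparseable elements are `NA`.
#' @export
parse_instant <- function(x) {
  if (inherits(x, "POSIXct")) return(canon_instant(x))
  if (is.numeric(x)) {
    return(canon_instant(as.POSIXct(x, origin = "1970-01-01", tz = "UTC")))
  }
  x <- as.character(x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  # each format is gated by a shape regex: strptime ignores trailing text,
  # so "31/05/2020" would otherwise match "%Y/%m/%d" as year 31
  fmts <- list(
    c("^\\d{4}-\\d{2}-\\d{2}T.*Z$",        "%Y-%m-%dT%H:%M:%OSZ"),
    c("^\\d{4}-\\d{2}-\\d{2}T.*[+-]\\d{4}$", "%Y-%m-%dT%H:%M:%OS%z"),
    c("^\\d{4}-\\d{2}-\\d{2}T",            "%Y-%m-%dT%H:%M:%OS"),
    c("^\\d{4}-\\d{2}-\\d{2} ",            "%Y-%m-%d %H:%M:%OS"),
    c("^\\d{4}-\\d{2}-\\d{2}$",            "%Y-%m-%d"),
    c("^\\d{4}/\\d{1,2}/\\d{1,2}$",        "%Y/%m/%d"),
    c("^\\d{1,2}/\\d{1,2}/\\d{4} ",        "%d/%m/%Y %H:%M:%OS"),
    c("^\\d{1,2}/\\d{1,2}/\\d{4}$",        "%d/%m/%Y"),
    c("^[A-Za-z]+ \\d{1,2},? \\d{4}$",     "%B %d %Y"),
    c("^[A-Za-z]+ \\d{1,2},? \\d{4}$",     "%b %d %Y"),
    c("^\\d{1,2} [A-Za-z]+ \\d{4}$",       "%d %B %Y"),
    c("^\\d{1,2} [A-Za-z]+ \\d{4}$",       "%d %b %Y")
  )
  todo <- !is.na(x) & nzchar(trimws(x))
  x[todo] <- trimws(x[todo])
  x <- sub(",", "", x, fixed = TRUE) # "May 31, 2020"
  for (f in fmts) {
    sel <- todo & grepl(f[1], x)
    if (!any(sel)) next
    got <- as.POSIXct(x[sel], format = f[2], tz = "UTC")
    hit <- !is.na(got)
    out[which(sel)[hit]] <- got[hit]
    todo[which(sel)[hit]] <- FALSE
  }
  canon_instant(out)
}

canon_instant <- function(t) {
  # millisecond grid keeps text serialization lossless
  as.POSIXct(round(as.numeric(t) * 1000) / 1000,
             origin = "1970-01-01", tz = "UTC")
}

#' Format an instant as canonical ISO-8601 UTC text
#' @param t POSIXct vector.
#' @return character vector like `"2024-01-01T00:00:00.000Z"`.
#' @export
format_instant <- function(t) {
  format(canon_instant(t), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

# full-precision decimal text for doubles (round-trips exactly)
fmt_double <- function(v) {
  vapply(v, function(x) {
    if (is.na(x)) return("NA")
    if (x == Inf) return("INF")
    if (x == -Inf) return("-INF")
    sprintf("%.17g", x)
  }, character(1))
}

parse_double <- function(s) {
  vapply(s, function(x) {
    if (x == "INF") return(Inf)
    if (x == "-INF") return(-Inf)
    as.numeric(x)
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vw_stop <- function(...) stop(sprintf(...), call. = FALSE)
vw_warn <- function(...) warning(sprintf(...), call. = FALSE)

# numeric comparison dispatch used by rule atoms and the simulator
compare_op <- function(x, op, const) {
  switch(op,
    "<"  = x < const,
    "<=" = x <= const,
    ">"  = x > const,
    ">=" = x >= const,
    "="  = x == const,
    vw_stop("unsupported comparison operator '%s'", op)
  )
}
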