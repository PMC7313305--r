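# Interval-set algebra behind abnormal-range axioms.
#
# A region is a finite union of real intervals, each bound tagged open or
# closed, bounds possibly infinite. Stored as a data.frame with columns
# lower, upper, lower_closed, upper_closed, kept normalized: sorted,
# pairwise disjoint, non-empty.

#' Construct an interval set
#'
#' @param lower,upper numeric vectors of bounds (may be `-Inf` / `Inf`).
#' @param lower_closed,upper_closed logical vectors (recycled); infinite
#'   bounds are forced open.
#' @return a normalized `vw_interval_set` data.frame.
#' @examples
#' interval_set(-Inf, 0.5)                      # the open half-line (-Inf, 0.5)
#' interval_set(c(0, 2), c(1, 3), TRUE, TRUE)   # [0,1] u [2,3]
#' @export
interval_set <- function(lower = numeric(), upper = numeric(),
                         lower_closed = FALSE, upper_closed = FALSE) {
  n <- length(lower)
  stopifnot(length(upper) == n)
  lower_closed <- rep_len(as.logical(lower_closed), n)
  upper_closed <- rep_len(as.logical(upper_closed), n)
  lower_closed[is.infinite(lower)] <- FALSE
  upper_closed[is.infinite(upper)] <- FALSE
  iv <- data.frame(lower = as.numeric(lower), upper = as.numeric(upper),
                   lower_closed = lower_closed, upper_closed = upper_closed)
  bad <- iv$lower > iv$upper |
    (iv$lower == iv$upper & !(iv$lower_closed & iv$upper_closed))
  if (any(bad)) vw_stop("empty interval: bounds [%s, %s]",
                        iv$lower[bad][1], iv$upper[bad][1])
  interval_normalize(iv)
}

#' @rdname interval_set
#' @param iv an interval-set data.frame (possibly unsorted / overlapping).
#' @export
interval_normalize <- function(iv) {
  iv <- as.data.frame(iv)
  if (nrow(iv) == 0) {
    iv <- data.frame(lower = numeric(), upper = numeric(),
                     lower_closed = logical(), upper_closed = logical())
    class(iv) <- c("vw_interval_set", "data.frame")
    return(iv)
  }
  # closed lower bound sorts before open at the same point
  iv <- iv[order(iv$lower, !iv$lower_closed), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    cur <- out[nrow(out), ]
    nxt <- iv[i, ]
    touches <- nxt$lower < cur$upper ||
      (nxt$lower == cur$upper && (nxt$lower_closed || cur$upper_closed))
    if (touches) {
      if (nxt$upper > cur$upper) {
        out[nrow(out), c("upper", "upper_closed")] <-
          list(nxt$upper, nxt$upper_closed)
      } else if (nxt$upper == cur$upper) {
        out[nrow(out), "upper_closed"] <- cur$upper_closed || nxt$upper_closed
      }
    } else {
      out <- rbind(out, nxt)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("vw_interval_set", "data.frame")
  out
}

#' Union of two interval sets
#' @param a,b interval sets.
#' @return normalized union.
#' @export
interval_union <- function(a, b) {
  interval_normalize(rbind(as.data.frame(a), as.data.frame(b)))
}

#' Membership test for an interval set
#' @param iv interval set.
#' @param x numeric vector.
#' @return logical vector, `TRUE` where `x` lies in the union.
#' @export
interval_contains <- function(iv, x) {
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(iv))) {
    lo_ok <- if (iv$lower_closed[i]) x >= iv$lower[i] else x > iv$lower[i]
    hi_ok <- if (iv$upper_closed[i]) x <= iv$upper[i] else x < iv$upper[i]
    hit <- hit | (lo_ok & hi_ok)
  }
  hit & !is.na(x)
}

interval_equal <- function(a, b) {
  a <- interval_normalize(a); b <- interval_normalize(b)
  nrow(a) == nrow(b) &&
    (nrow(a) == 0 || (all(a$lower == b$lower) && all(a$upper == b$upper) &&
       all(a$lower_closed == b$lower_closed) &&
       all(a$upper_closed == b$upper_closed)))
}

# validator used by tests: sorted, disjoint, non-empty
interval_is_normalized <- function(iv) {
  if (nrow(iv) == 0) return(TRUE)
  ok_each <- iv$lower < iv$upper |
    (iv$lower == iv$upper & iv$lower_closed & iv$upper_closed)
  if (!all(ok_each)) return(FALSE)
  if (nrow(iv) == 1) return(TRUE)
  for (i in 2:nrow(iv)) {
    prev <- iv[i - 1, ]; cur <- iv[i, ]
    sep <- cur$lower > prev$upper ||
      (cur$lower == prev$upper && !cur$lower_closed && !prev$upper_closed)
    if (!sep) return(FALSE)
  }
  TRUE
}
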