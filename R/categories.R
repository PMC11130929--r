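#' Category grids for 12-month partner counts
#'
#' EMIS-style survey instruments record 12-month partner numbers on ordinal
#' grids rather than as integers: steady partners as 0, 1, ..., 9 or "10+",
#' and casual partners as 0, 1, ..., 10 followed by the interval categories
#' "11-20", "21-30", "31-40", "41-50" and ">50". The total-partner grid used
#' when summing steady and casual counts shares the casual grid's interval
#' categories.
#'
#' @param cap Upper bound given to the open-ended ">50" category so that the
#'   heavy tail has finite support (default 300).
#' @return Character vector of labels (`steady_levels`, `casual_levels`) or a
#'   two-column matrix of inclusive integer bounds (`category_bounds`).
#' @name category-grids
NULL

#' @rdname category-grids
#' @export
steady_levels <- function() c(as.character(0:9), "10+")

#' @rdname category-grids
#' @export
casual_levels <- function() {
  c(as.character(0:10), "11-20", "21-30", "31-40", "41-50", ">50")
}

.interval_levels <- c("11-20", "21-30", "31-40", "41-50", ">50")

#' @rdname category-grids
#' @param labels Character vector of category labels.
#' @export
category_bounds <- function(labels, cap = 300) {
  lo <- integer(length(labels))
  hi <- integer(length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    if (lab == ">50") {
      lo[k] <- 51L
      hi[k] <- as.integer(cap)
    } else if (lab == "10+") {
      lo[k] <- 10L
      hi[k] <- 12L # at most 12 steady partners over 12 months
    } else if (grepl("-", lab, fixed = TRUE)) {
      parts <- as.integer(strsplit(lab, "-", fixed = TRUE)[[1]])
      lo[k] <- parts[1]
      hi[k] <- parts[2]
    } else {
      lo[k] <- hi[k] <- as.integer(lab)
    }
  }
  cbind(lo = lo, hi = hi)
}

#' Categorise integer partner counts on the casual/total grid
#'
#' Inverse of the survey's interval censoring: exact labels for counts up to
#' 10, interval labels above. Values above `cap` are folded into ">50".
#'
#' @param x Non-negative integer counts.
#' @inheritParams category-grids
#' @return Character vector of labels from [casual_levels()].
#' @export
casual_category <- function(x, cap = 300) {
  stopifnot(all(x >= 0))
  out <- character(length(x))
  out[x <= 10] <- as.character(x[x <= 10])
  out[x > 10 & x <= 20] <- "11-20"
  out[x > 20 & x <= 30] <- "21-30"
  out[x > 30 & x <= 40] <- "31-40"
  out[x > 40 & x <= 50] <- "41-50"
  out[x > 50] <- ">50"
  out
}

#' Categorise steady partner counts
#' @inheritParams casual_category
#' @return Character vector of labels from [steady_levels()].
#' @export
steady_category <- function(x) {
  stopifnot(all(x >= 0))
  ifelse(x >= 10, "10+", as.character(x))
}

# --- truncated discrete normal -----------------------------------------------
#
# Within-category integer draws use a discretised normal restricted to the
# category bounds. Truncation shifts the first moment, so the location
# parameter is re-solved (uniroot) such that the *truncated* mean equals the
# requested target; the scale is kept at the target SD. When the target mean
# falls outside [lo, hi] the nearest attainable mean is used.

.dtnorm_weights <- function(lo, hi, mu, sd) {
  x <- lo:hi
  if (sd <= 0) {
    w <- as.numeric(x == round(mu))
    if (sum(w) == 0) w[which.min(abs(x - mu))] <- 1
    return(w)
  }
  w <- stats::pnorm(x + 0.5, mu, sd) - stats::pnorm(x - 0.5, mu, sd)
  if (sum(w) <= 0) { # numerically degenerate: fall back to nearest point
    w <- numeric(length(x))
    w[which.min(abs(x - mu))] <- 1
  }
  w
}

.tnorm_mean <- function(lo, hi, mu, sd) {
  w <- .dtnorm_weights(lo, hi, mu, sd)
  sum((lo:hi) * w) / sum(w)
}

#' Probability mass of the moment-matched truncated discrete normal
#'
#' Discretised normal on the integers of `[lo, hi]` whose location is solved
#' so that the truncated mean equals `mean` (clamped to the attainable range).
#'
#' @param lo,hi Inclusive integer support bounds.
#' @param mean,sd Target first two moments (the SD is not re-corrected after
#'   truncation).
#' @return Numeric vector of probabilities over `lo:hi`.
#' @export
dtnorm_pmf <- function(lo, hi, mean, sd) {
  stopifnot(hi >= lo)
  if (lo == hi) return(1)
  target <- min(max(mean, lo), hi)
  if (sd <= 0) {
    w <- .dtnorm_weights(lo, hi, target, 0)
    return(w / sum(w))
  }
  span <- 6 * sd + (hi - lo)
  f <- function(m) .tnorm_mean(lo, hi, m, sd) - target
  f_lo <- f(lo - span)
  f_hi <- f(hi + span)
  mu <- if (f_lo >= 0) lo - span
        else if (f_hi <= 0) hi + span
        else stats::uniroot(f, c(lo - span, hi + span), tol = 1e-6)$root
  w <- .dtnorm_weights(lo, hi, mu, sd)
  w / sum(w)
}

#' Sample moment-matched truncated discrete integers
#'
#' @inheritParams dtnorm_pmf
#' @param n Number of draws.
#' @return Integer vector of length `n` within `[lo, hi]`.
#' @export
rtnorm_int <- function(n, lo, hi, mean, sd) {
  if (n == 0) return(integer(0))
  p <- dtnorm_pmf(lo, hi, mean, sd)
  (lo:hi)[sample.int(hi - lo + 1L, n, replace = TRUE, prob = p)]
}
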