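#' Target statistics for integer partner-count reconstruction
#'
#' Container for the per-category and overall summary statistics that the
#' reconstruction algorithm must match: mean, SD, median and interquartile
#' range of the number of partners in the past 12 months, overall and for
#' each interval category of the total-partner grid. Defaults are the
#' published target values for the Belgian MSM population (overall mean 15.8,
#' SD 36.60, median 5, IQR 2-15; per-category means/SDs 16.4/3.30, 27.8/2.80,
#' 38.6/2.40, 49.6/1.50 and 128.2/98.10 for "11-20" through ">50").
#'
#' @param overall Named list with `mean`, `sd`, `median`, `q1`, `q3`.
#' @param categories Data frame with columns `label`, `mean`, `sd`, `median`,
#'   `q1`, `q3`, one row per interval category.
#' @return An object of class `category_targets`.
#' @export
category_targets <- function(overall = list(mean = 15.8, sd = 36.60,
                                            median = 5, q1 = 2, q3 = 15),
                             categories = data.frame(
                               label  = c("11-20", "21-30", "31-40",
                                          "41-50", ">50"),
                               mean   = c(16.4, 27.8, 38.6, 49.6, 128.2),
                               sd     = c(3.30, 2.80, 2.40, 1.50, 98.10),
                               median = c(15, 30, 40, 50, 100),
                               q1     = c(14, 25, 37, 50, 75),
                               q3     = c(20, 30, 40, 50, 150))) {
  stopifnot(is.list(overall),
            all(c("mean", "sd", "median", "q1", "q3") %in% names(overall)),
            overall$sd >= 0, overall$q1 <= overall$median,
            overall$median <= overall$q3,
            is.data.frame(categories),
            all(categories$sd >= 0),
            all(categories$q1 <= categories$median),
            all(categories$median <= categories$q3))
  bounds <- category_bounds(categories$label)
  if (any(categories$mean < bounds[, "lo"] | categories$mean > bounds[, "hi"]))
    stop("impossible targets: a category target mean lies outside its bounds")
  structure(list(overall = overall, categories = categories),
            class = "category_targets")
}

#' Resolve the total-partner category for one respondent
#'
#' A respondent's total partner number is the sum of steady and casual
#' partners. For casual counts reported exactly (<= 10) the total is exact.
#' For interval casual categories the feasible range of the total,
#' `[steady + lo, steady + hi]`, is intersected with the total-partner grid;
#' when it spans two grid categories one is selected at random with
#' probability proportional to the number of overlapping integers.
#'
#' @param steady_count Integer number of steady partners.
#' @param casual_category Casual category label (see [casual_levels()]).
#' @param cap Upper bound of the ">50" casual category.
#' @return For exact casual counts, a list with `total` (integer). For
#'   interval categories, a list with `label` (selected total category),
#'   `window` (integer bounds of the feasible totals inside it) and
#'   `prob` (named selection probabilities over the candidate categories).
#' @export
resolve_total_category <- function(steady_count, casual_category, cap = 300) {
  stopifnot(length(steady_count) == 1, steady_count >= 0,
            casual_category %in% casual_levels())
  if (!casual_category %in% .interval_levels) {
    return(list(total = as.integer(steady_count) +
                  as.integer(casual_category)))
  }
  cb <- category_bounds(casual_category, cap = cap)
  rng <- c(steady_count + cb[1, "lo"], steady_count + cb[1, "hi"])
  cand <- .total_grid_overlap(rng, cap = cap)
  lab <- if (nrow(cand) == 1) cand$label else
    sample(cand$label, 1, prob = cand$prob)
  row <- cand[cand$label == lab, ]
  list(label = lab, window = c(row$lo, row$hi),
       prob = stats::setNames(cand$prob, cand$label))
}

# Overlap of an integer range with the interval categories of the total grid.
# The ">50" total category extends to cap + 12 (casual cap plus the steady
# maximum) so any feasible total has a home.
.total_grid_overlap <- function(rng, cap = 300) {
  grid <- data.frame(label = .interval_levels,
                     category_bounds(.interval_levels, cap = cap))
  grid$hi[grid$label == ">50"] <- cap + 12L
  lo <- pmax(grid$lo, rng[1])
  hi <- pmin(grid$hi, rng[2])
  keep <- hi >= lo
  n <- hi - lo + 1L
  out <- data.frame(label = grid$label[keep], lo = lo[keep], hi = hi[keep],
                    prob = n[keep] / sum(n[keep]),
                    stringsAsFactors = FALSE)
  out
}

#' Assign integer 12-month partner counts to categorical responses
#'
#' Iterative reconstruction of integer total-partner counts from the
#' categorical steady and casual responses of a survey, targeting published
#' summary statistics. Each iteration (a) reassigns respondents reporting
#' "10+" steady partners uniformly to 10, 11 or 12; (b) takes exact totals
#' for casual counts reported as integers (<= 10); (c) for interval casual
#' categories selects a total-partner category by range overlap
#' ([resolve_total_category()]) and draws an integer from a moment-matched
#' truncated discrete normal with the category's target mean and SD,
#' restricted to totals compatible with the reported casual bounds; then
#' (d) compares achieved means and the overall median to the targets. The
#' absolute error sum is the sum of |achieved - target| over the overall
#' mean, the overall median and the per-category means; iteration stops when
#' it falls below `tol` (default 1.5) or `max_iter` is reached, returning the
#' best draw seen.
#'
#' Per-category achieved statistics are computed over the respondents whose
#' totals were drawn (interval-category responses), grouped by the assigned
#' total category; exact totals contribute to the overall statistics only.
#'
#' @param survey Data frame with columns `steady_count_category` and
#'   `casual_count_category` (e.g. from [generate_survey()]).
#' @param targets A [category_targets()] object.
#' @param seed Optional integer seed making the reconstruction reproducible.
#' @param max_iter Maximum number of redraw iterations.
#' @param tol Absolute error-sum threshold for convergence.
#' @param cap Upper bound of the ">50" casual category.
#' @return An object of class `recon_result`: list with `counts` (data frame
#'   of per-respondent `steady`, `casual`, `total`, `total_category`,
#'   `drawn`), `achieved` (overall and per-category statistics of the best
#'   draw), `error` (final absolute error sum), `error_trace` (best error
#'   after each iteration), `iterations`, `converged`.
#' @export
assign_integer_counts <- function(survey, targets = category_targets(),
                                  seed = NULL, max_iter = 2000, tol = 1.5,
                                  cap = 300) {
  stopifnot(inherits(targets, "category_targets"),
            all(c("steady_count_category", "casual_count_category")
                %in% names(survey)))
  if (!all(survey$steady_count_category %in% steady_levels()))
    stop("invalid steady category label")
  if (!all(survey$casual_count_category %in% casual_levels()))
    stop("invalid casual category label")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(survey)
  if (n == 0) stop("empty survey")
  scat <- survey$steady_count_category
  ccat <- survey$casual_count_category
  ten_plus <- scat == "10+"
  steady_base <- rep(NA_integer_, n)
  steady_base[!ten_plus] <- as.integer(scat[!ten_plus])
  exact <- !(ccat %in% .interval_levels)
  casual_exact <- rep(NA_integer_, n)
  casual_exact[exact] <- as.integer(ccat[exact])

  tg_cat <- targets$categories
  tg_mean <- stats::setNames(tg_cat$mean, tg_cat$label)
  tg_sd <- stats::setNames(tg_cat$sd, tg_cat$label)

  pmf_cache <- new.env(parent = emptyenv())
  window_pmf <- function(lo, hi, m, s) {
    key <- paste(lo, hi, round(m, 2), sep = "_")
    p <- pmf_cache[[key]]
    if (is.null(p)) {
      p <- dtnorm_pmf(lo, hi, round(m, 2), s)
      pmf_cache[[key]] <- p
    }
    p
  }

  # candidate total categories are fixed per respondent unless the steady
  # count is redrawn ("10+"), so precompute the assignment groups once
  idx_int <- which(!exact)
  fixed_int <- idx_int[!ten_plus[idx_int]]
  float_int <- idx_int[ten_plus[idx_int]]
  combo_groups <- list()
  if (length(fixed_int) > 0) {
    combo <- paste(ccat[fixed_int], steady_base[fixed_int])
    for (cb in unique(combo)) {
      rows <- fixed_int[combo == cb]
      s <- steady_base[rows[1]]
      bounds <- category_bounds(ccat[rows[1]], cap = cap)
      cand <- .total_grid_overlap(c(s + bounds[1, "lo"],
                                    s + bounds[1, "hi"]), cap = cap)
      combo_groups[[cb]] <- list(rows = rows, cand = cand)
    }
  }

  best <- NULL
  trace <- numeric(0)
  iter <- 0
  converged <- FALSE

  while (iter < max_iter) {
    iter <- iter + 1
    steady <- steady_base
    k10 <- sum(ten_plus)
    if (k10 > 0) steady[ten_plus] <- sample(10:12, k10, replace = TRUE)
    total <- integer(n)
    total[exact] <- steady[exact] + casual_exact[exact]
    tot_cat <- rep(NA_character_, n)

    # assign a total category and feasible window to every interval response
    win_lo <- integer(n); win_hi <- integer(n)
    assign_from <- function(rows, cand) {
      pick <- if (nrow(cand) == 1) rep(1L, length(rows)) else
        sample.int(nrow(cand), length(rows), replace = TRUE,
                   prob = cand$prob)
      tot_cat[rows] <<- cand$label[pick]
      win_lo[rows] <<- cand$lo[pick]
      win_hi[rows] <<- cand$hi[pick]
    }
    for (g in combo_groups) assign_from(g$rows, g$cand)
    for (r in float_int) {
      bounds <- category_bounds(ccat[r], cap = cap)
      cand <- .total_grid_overlap(c(steady[r] + bounds[1, "lo"],
                                    steady[r] + bounds[1, "hi"]), cap = cap)
      assign_from(r, cand)
    }

    # draw totals per category: narrow windows clamp the attainable mean, so
    # the target for the unclamped windows is adjusted to keep the category's
    # expected mean on target
    for (lab in tg_cat$label) {
      rows <- idx_int[tot_cat[idx_int] == lab]
      if (length(rows) == 0) next
      tgm <- tg_mean[[lab]]; tgs <- tg_sd[[lab]]
      wkey <- paste(win_lo[rows], win_hi[rows])
      uw <- !duplicated(wkey)
      wlo <- win_lo[rows][uw]; whi <- win_hi[rows][uw]
      nw <- as.numeric(table(wkey)[paste(wlo, whi)])
      mw <- vapply(seq_along(wlo), function(k) {
        p <- window_pmf(wlo[k], whi[k], tgm, tgs)
        sum((wlo[k]:whi[k]) * p)
      }, numeric(1))
      t_use <- rep(tgm, length(wlo))
      adj <- abs(mw - tgm) < 0.01
      if (any(adj) && !all(adj)) {
        t2 <- tgm + (tgm * sum(nw) - sum(nw * mw)) / sum(nw[adj])
        t_use[adj] <- t2
      }
      for (k in seq_along(wlo)) {
        rr <- rows[wkey == paste(wlo[k], whi[k])]
        p <- window_pmf(wlo[k], whi[k], t_use[k], tgs)
        total[rr] <- (wlo[k]:whi[k])[
          sample.int(whi[k] - wlo[k] + 1L, length(rr), replace = TRUE,
                     prob = p)]
      }
    }

    ov_mean <- mean(total)
    ov_med <- stats::median(total)
    err <- abs(ov_mean - targets$overall$mean) +
      abs(ov_med - targets$overall$median)
    for (lab in tg_cat$label) {
      v <- total[idx_int][tot_cat[idx_int] == lab]
      if (length(v) > 0) err <- err + abs(mean(v) - tg_mean[[lab]])
    }

    if (is.null(best) || err < best$error) {
      best <- list(error = err, steady = steady, total = total,
                   tot_cat = tot_cat, iterations = iter)
    }
    trace <- c(trace, best$error)
    if (best$error < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf(
      "reconstruction did not reach error < %.3g in %d iterations (best %.3g)",
      tol, max_iter, best$error))

  total <- best$total
  steady <- best$steady
  tot_cat_final <- ifelse(is.na(best$tot_cat),
                          casual_category(total, cap = cap + 12L),
                          best$tot_cat)
  ach_cat <- do.call(rbind, lapply(tg_cat$label, function(lab) {
    v <- total[!exact & best$tot_cat == lab & !is.na(best$tot_cat)]
    if (length(v) == 0) return(NULL)
    data.frame(label = lab, n = length(v), mean = mean(v),
               sd = stats::sd(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)))
  }))
  counts <- data.frame(
    respondent_id = if ("respondent_id" %in% names(survey))
      survey$respondent_id else seq_len(n),
    steady = steady,
    casual = total - steady,
    total = total,
    total_category = tot_cat_final,
    drawn = !exact,
    stringsAsFactors = FALSE)

  structure(list(
    counts = counts,
    achieved = list(
      overall = list(mean = mean(total), sd = stats::sd(total),
                     median = stats::median(total),
                     q1 = unname(stats::quantile(total, 0.25)),
                     q3 = unname(stats::quantile(total, 0.75))),
      categories = ach_cat),
    error = best$error,
    error_trace = trace,
    iterations = iter,
    converged = converged,
    targets = targets), class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "Partner-count reconstruction: %d respondents, error sum %.3f (%s, %d iterations)\n",
    nrow(x$counts), x$error,
    if (x$converged) "converged" else "not converged", x$iterations))
  cat(sprintf("  overall mean %.2f (target %.2f), median %g (target %g)\n",
              x$achieved$overall$mean, x$targets$overall$mean,
              x$achieved$overall$median, x$targets$overall$median))
  invisible(x)
}

#' Split casual partners into one-off and persistent casual
#'
#' The one-off number is the casual count multiplied by the population
#' fraction whose last sexual encounter was a one-off, rounded half-to-even
#' (base R rounding); the remainder are persistent casual partners.
#'
#' @param casual_count Non-negative integer vector of casual partner counts.
#' @param one_off_fraction Fraction in `[0, 1]`.
#' @return Data frame with integer columns `one_off` and `persistent`.
#' @export
split_casual <- function(casual_count, one_off_fraction) {
  stopifnot(one_off_fraction >= 0, one_off_fraction <= 1,
            all(casual_count >= 0))
  one_off <- as.integer(round(casual_count * one_off_fraction))
  data.frame(one_off = one_off,
             persistent = as.integer(casual_count) - one_off)
}

#' Reconstruct integer partner counts and split them by partnership type
#'
#' Convenience wrapper running [assign_integer_counts()] and
#' [split_casual()], attaching per-respondent steady, persistent-casual and
#' one-off counts.
#'
#' @inheritParams assign_integer_counts
#' @param one_off_fraction Fraction of casual partners that were one-off
#'   encounters; defaults to the generating configuration's value when the
#'   survey carries one, else 0.5.
#' @return A `recon_result` whose `counts` gains `one_off` and `persistent`
#'   columns.
#' @export
reconstruct_survey <- function(survey, targets = category_targets(),
                               one_off_fraction = NULL, seed = NULL,
                               max_iter = 2000, tol = 1.5, cap = 300) {
  if (is.null(one_off_fraction)) {
    cfg <- attr(survey, "config")
    one_off_fraction <- if (!is.null(cfg)) cfg$one_off_fraction else 0.5
  }
  res <- assign_integer_counts(survey, targets = targets, seed = seed,
                               max_iter = max_iter, tol = tol, cap = cap)
  sp <- split_casual(res$counts$casual, one_off_fraction)
  res$counts$one_off <- sp$one_off
  res$counts$persistent <- sp$persistent
  res$one_off_fraction <- one_off_fraction
  res
}

#' Summarise cumulative 12-month partner counts by group and type
#'
#' Medians and interquartile ranges of the per-respondent steady,
#' persistent-casual and one-off partner counts, by activity group. These
#' tables are the calibration targets for the network model. Quantiles use
#' the linear-interpolation definition (R type 7) throughout.
#'
#' @param result A `recon_result` from [reconstruct_survey()].
#' @param groups Character vector ("HA"/"LA") of length `nrow(result$counts)`.
#' @return A `partner_summary` data frame with columns `group`, `type`,
#'   `median`, `q1`, `q3`.
#' @export
target_summaries <- function(result, groups) {
  stopifnot(inherits(result, "recon_result"),
            length(groups) == nrow(result$counts),
            all(groups %in% c("HA", "LA")),
            all(c("one_off", "persistent") %in% names(result$counts)))
  cols <- c(steady = "steady", casual = "persistent", oneoff = "one_off")
  out <- expand.grid(group = c("HA", "LA"), type = names(cols),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$median <- out$q1 <- out$q3 <- NA_real_
  for (r in seq_len(nrow(out))) {
    v <- result$counts[[cols[[out$type[r]]]]][groups == out$group[r]]
    if (length(v) == 0) stop("empty group: ", out$group[r])
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    out$q1[r] <- q[1]; out$median[r] <- q[2]; out$q3[r] <- q[3]
  }
  partner_summary(out)
}

#' Construct a partner-summary table
#'
#' Shared container for group x partnership-type quantile summaries of
#' cumulative 12-month partner counts, produced both from reconstructed
#' survey counts ([target_summaries()]) and from simulated networks
#' ([measure_cumulative_partners()]).
#'
#' @param df Data frame with columns `group`, `type`, `median`, `q1`, `q3`.
#' @return The data frame, ordered canonically, with class `partner_summary`.
#' @export
partner_summary <- function(df) {
  stopifnot(all(c("group", "type", "median", "q1", "q3") %in% names(df)))
  df <- df[order(df$group, df$type),
           c("group", "type", "median", "q1", "q3")]
  rownames(df) <- NULL
  class(df) <- c("partner_summary", "data.frame")
  df
}
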