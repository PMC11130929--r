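#' Uniform prior specification for the calibrated parameters
#'
#' Seven parameters are calibrated: the mean steady-partnership duration,
#' the mean persistent-casual durations for HA-HA, LA-LA and mixed pairs,
#' and the HA homophily rates of the steady, casual and one-off layers (the
#' LA rates are derived through the balance equation). Default bounds depend
#' on the activity-group scenario.
#'
#' @param scenario Scenario name (see [scenario_targets()]).
#' @param override Optional named list of `c(lower, upper)` pairs replacing
#'   individual defaults.
#' @return Object of class `prior_spec`: data frame with `name`, `lower`,
#'   `upper`.
#' @export
prior_spec <- function(scenario = c("prep_eligibility", "gt15_total",
                                    "gt15_casual"),
                       override = NULL) {
  scenario <- match.arg(scenario)
  prep <- scenario == "prep_eligibility"
  df <- data.frame(
    name = c("dur_steady", "dur_casual_hh", "dur_casual_ll",
             "dur_casual_hl", "h_steady", "h_casual", "h_oneoff"),
    lower = c(800, if (prep) 4 else 3, 15, if (prep) 10 else 5,
              0.55, if (scenario == "gt15_total") 0.60 else 0.45, 0.45),
    upper = c(2000, if (prep) 15 else 100, 500, if (prep) 30 else 100,
              1, 1, 1),
    stringsAsFactors = FALSE)
  if (!is.null(override)) {
    for (nm in names(override)) {
      stopifnot(nm %in% df$name, length(override[[nm]]) == 2)
      df[df$name == nm, c("lower", "upper")] <- as.list(override[[nm]])
    }
  }
  stopifnot(all(df$lower < df$upper))
  class(df) <- c("prior_spec", "data.frame")
  df
}

#' Distance between two partner-summary tables
#'
#' Normalised L1 distance over the group x type x {median, q1, q3} cells:
#' `sum(|sim - target| / max(target, 1))`. The normalisation balances the
#' small steady counts against the large one-off counts; the floor of 1
#' keeps zero-valued target cells from dominating. Zero iff the tables are
#' identical; invariant under row reordering.
#'
#' @param simulated,target [partner_summary()] tables over the same
#'   group x type cells.
#' @return Non-negative scalar.
#' @export
summary_distance <- function(simulated, target) {
  key <- function(d) paste(d$group, d$type)
  if (nrow(simulated) != nrow(target) ||
      !setequal(key(simulated), key(target)))
    stop("summary tables do not share the same group x type cells")
  m <- match(key(target), key(simulated))
  d <- 0
  for (col in c("median", "q1", "q3")) {
    tv <- target[[col]]
    d <- d + sum(abs(simulated[[col]][m] - tv) / pmax(tv, 1))
  }
  d
}

#' Weighted quantiles with linear interpolation
#'
#' Quantiles of a weighted sample, interpolating linearly between order
#' statistics at their cumulative-weight midpoints; particles with zero
#' weight are ignored.
#'
#' @param x Numeric values.
#' @param w Non-negative weights.
#' @param probs Probabilities.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  if (length(x) == 1) return(rep(x, length(probs)))
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

.runif_prior <- function(n, priors) {
  m <- vapply(seq_len(nrow(priors)), function(k)
    stats::runif(n, priors$lower[k], priors$upper[k]), numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- priors$name
  m
}

.sim_distance <- function(simulator, theta, target) {
  s <- tryCatch(simulator(theta),
                error = function(e)
                  stop(sprintf("simulator failed at [%s]: %s",
                               paste(sprintf("%s=%.4g", names(theta), theta),
                                     collapse = ", "),
                               conditionMessage(e)), call. = FALSE))
  if (is.null(s)) return(Inf)
  summary_distance(s, target)
}

#' Adaptive ABC-SMC calibration (population Monte Carlo)
#'
#' Likelihood-free estimation of the network parameters by an adaptive
#' sequential Monte Carlo scheme: an initial generation of
#' `n_particles / alpha` prior draws is simulated and the `alpha` fraction
#' with the smallest distances kept; each subsequent generation perturbs
#' weighted ancestors with a component-wise normal kernel whose variance is
#' twice the weighted empirical variance (truncated to the prior support by
#' resampling), re-simulates, merges with the surviving particles and keeps
#' the best `n_particles`. Sampling stops when the proportion of newly drawn
#' particles beating the previous distance threshold falls below
#' `p_acc_min`, or after `max_gen` generations.
#'
#' @param priors A [prior_spec()].
#' @param simulator Function mapping a named parameter vector to a
#'   [partner_summary()] (or `NULL` for an infeasible parameter vector,
#'   treated as infinite distance). Errors abort the run with the offending
#'   parameter vector reported.
#' @param target Target [partner_summary()].
#' @param n_particles Number of retained particles (>= 50 for production
#'   use; smaller values are allowed for smoke tests).
#' @param alpha Fraction of simulations kept per generation.
#' @param p_acc_min Stopping threshold on the acceptance proportion.
#' @param max_gen Maximum number of perturbation generations.
#' @param seed Optional RNG seed.
#' @param verbose Print per-generation progress.
#' @return Object of class `abc_posterior`: list with `particles` (matrix),
#'   `weights`, `distances`, `eps_trace`, `p_acc_trace`, `generations`,
#'   `n_simulations`, `priors`.
#' @export
abc_smc <- function(priors, simulator, target, n_particles = 100,
                    alpha = 0.5, p_acc_min = 0.05, max_gen = 8,
                    seed = NULL, verbose = FALSE) {
  stopifnot(inherits(priors, "prior_spec"), n_particles >= 2,
            alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(priors)
  n0 <- ceiling(n_particles / alpha)
  theta <- .runif_prior(n0, priors)
  dist <- vapply(seq_len(n0), function(r)
    .sim_distance(simulator, theta[r, ], target), numeric(1))
  n_sims <- n0
  keep <- order(dist)[seq_len(n_particles)]
  theta <- theta[keep, , drop = FALSE]
  dist <- dist[keep]
  w <- rep(1 / n_particles, n_particles)
  eps <- max(dist)
  eps_trace <- eps
  p_acc_trace <- numeric(0)
  gen <- 0

  while (gen < max_gen) {
    gen <- gen + 1
    wv <- vapply(seq_len(p), function(k) {
      mu <- sum(w * theta[, k])
      sum(w * (theta[, k] - mu)^2)
    }, numeric(1))
    sdk <- sqrt(pmax(2 * wv, 1e-12))
    n_new <- n0 - n_particles
    anc <- sample.int(n_particles, n_new, replace = TRUE, prob = w)
    prop <- theta[anc, , drop = FALSE] +
      matrix(stats::rnorm(n_new * p), n_new, p) %*% diag(sdk, p)
    for (k in seq_len(p)) { # truncate to the prior box by resampling
      bad <- which(prop[, k] < priors$lower[k] | prop[, k] > priors$upper[k])
      tries <- 0
      while (length(bad) > 0 && tries < 100) {
        prop[bad, k] <- theta[anc[bad], k] +
          stats::rnorm(length(bad), 0, sdk[k])
        bad <- bad[prop[bad, k] < priors$lower[k] |
                     prop[bad, k] > priors$upper[k]]
        tries <- tries + 1
      }
      if (length(bad) > 0)
        prop[bad, k] <- pmin(pmax(prop[bad, k], priors$lower[k]),
                             priors$upper[k])
    }
    colnames(prop) <- priors$name
    dist_new <- vapply(seq_len(n_new), function(r)
      .sim_distance(simulator, prop[r, ], target), numeric(1))
    n_sims <- n_sims + n_new
    p_acc <- mean(dist_new < eps)
    p_acc_trace <- c(p_acc_trace, p_acc)

    all_theta <- rbind(theta, prop)
    all_dist <- c(dist, dist_new)
    keep <- order(all_dist)[seq_len(n_particles)]
    theta_prev <- theta; w_prev <- w
    theta <- all_theta[keep, , drop = FALSE]
    dist <- all_dist[keep]
    # importance weights of the retained set against the previous
    # generation's perturbation mixture (uniform prior: constant numerator)
    sdm <- matrix(sdk, n_particles, p, byrow = TRUE)
    w <- vapply(seq_len(n_particles), function(r) {
      dens <- w_prev * exp(rowSums(stats::dnorm(
        sweep(theta_prev, 2, theta[r, ]), 0, sdm, log = TRUE)))
      1 / max(sum(dens), 1e-300)
    }, numeric(1))
    if (!all(is.finite(w)) || sum(w) <= 0) w <- rep(1, n_particles)
    w <- w / sum(w)
    eps <- max(dist)
    eps_trace <- c(eps_trace, eps)
    if (verbose)
      message(sprintf("generation %d: eps = %.4f, p_acc = %.3f",
                      gen, eps, p_acc))
    if (p_acc < p_acc_min) break
  }
  structure(list(particles = theta, weights = w, distances = dist,
                 eps_trace = eps_trace, p_acc_trace = p_acc_trace,
                 generations = gen, n_simulations = n_sims,
                 priors = priors),
            class = "abc_posterior")
}

#' Weighted posterior summary
#'
#' Per-parameter weighted mean and 95% credible interval (weighted 2.5th and
#' 97.5th percentiles).
#'
#' @param post An `abc_posterior`.
#' @return Data frame with `name`, `mean`, `ci_low`, `ci_high`.
#' @export
posterior_summary <- function(post) {
  stopifnot(inherits(post, "abc_posterior"))
  out <- data.frame(name = colnames(post$particles),
                    mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    x <- post$particles[, k]
    out$mean[k] <- sum(post$weights * x)
    q <- weighted_quantile(x, post$weights, c(0.025, 0.975))
    out$ci_low[k] <- q[1]; out$ci_high[k] <- q[2]
  }
  out
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf(
    "ABC-SMC posterior: %d particles, %d generations, %d simulations\n",
    nrow(x$particles), x$generations, x$n_simulations))
  print(posterior_summary(x), digits = 4)
  invisible(x)
}

#' Calibration report in the published table layout
#'
#' One row per calibrated parameter with its prior, weighted posterior mean
#' and 95% CI; the derived LA homophily rates (computed per particle through
#' the balance equation) are appended and flagged "Calculated from network".
#'
#' @param post An `abc_posterior` over the seven network parameters.
#' @param scenario Scenario name used for the row labels.
#' @param mixing Optional list of per-layer mixing degrees, as the `deg`
#'   element of [formation_targets_from_survey()], together with group
#'   counts: `list(n_ha =, n_la =, deg = list(steady =, casual =, oneoff =))`.
#'   When supplied, derived LA rows are appended.
#' @return Data frame with `parameter`, `prior`, `mean`, `ci_low`,
#'   `ci_high`, `note`.
#' @export
posterior_table <- function(post, scenario = "prep_eligibility",
                            mixing = NULL) {
  ps <- posterior_summary(post)
  pr <- post$priors
  labels <- c(
    dur_steady = "Average duration of steady partnerships (in days)",
    dur_casual_hh = "Average duration of casual partnerships, two HA-MSM (in days)",
    dur_casual_ll = "Average duration of casual partnerships, two LA-MSM (in days)",
    dur_casual_hl = "Average duration of casual partnerships, an LA- and a HA-MSM (in days)",
    h_steady = "Homophily rate, steady, HA-MSM",
    h_casual = "Homophily rate, casual, HA-MSM",
    h_oneoff = "Homophily rate, one-off, HA-MSM")
  out <- data.frame(
    parameter = unname(labels[ps$name]),
    prior = sprintf("Uniform (%g, %g)", pr$lower[match(ps$name, pr$name)],
                    pr$upper[match(ps$name, pr$name)]),
    mean = ps$mean, ci_low = ps$ci_low, ci_high = ps$ci_high,
    note = "", stringsAsFactors = FALSE)
  if (!is.null(mixing)) {
    la_labels <- c(h_steady = "Homophily rate, steady, LA-MSM",
                   h_casual = "Homophily rate, casual, LA-MSM",
                   h_oneoff = "Homophily rate, one-off, LA-MSM")
    layer_of <- c(h_steady = "steady", h_casual = "casual",
                  h_oneoff = "oneoff")
    for (nm in names(la_labels)) {
      d <- mixing$deg[[layer_of[[nm]]]]
      h_la <- vapply(post$particles[, nm], function(h)
        tryCatch(la_homophily(mixing_inputs(mixing$n_ha, mixing$n_la,
                                            d[["ha"]], d[["la"]], h)),
                 error = function(e) NA_real_), numeric(1))
      ok <- !is.na(h_la) & post$weights > 0
      if (!any(ok)) next
      wm <- sum(post$weights[ok] * h_la[ok]) / sum(post$weights[ok])
      q <- weighted_quantile(h_la[ok], post$weights[ok], c(0.025, 0.975))
      out <- rbind(out, data.frame(
        parameter = unname(la_labels[nm]), prior = "-", mean = wm,
        ci_low = q[1], ci_high = q[2], note = "Calculated from network",
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Build a network-model simulator for calibration
#'
#' Closes over the data-derived quantities (population, layer edge targets,
#' per-group mixing degrees, concurrency targets) and returns a function
#' mapping the 7-dimensional parameter vector to the simulated
#' cumulative-partner summary, averaged over `replicates` independent
#' network runs. Parameter vectors whose HA homophily rate is infeasible
#' under the balance equation (implied LA rate below zero) return `NULL`,
#' which the calibration treats as an infinite distance: such mixings cannot
#' exist in a closed population and receive zero posterior support.
#'
#' @param pop A [population()].
#' @param edges Per-layer edge-count targets (list with `steady`, `casual`,
#'   `oneoff`).
#' @param deg Per-layer per-group mean degrees, `list(steady = c(ha =, la =),
#'   ...)`, used in the balance equation.
#' @param days Days simulated per run.
#' @param replicates Independent runs averaged per parameter vector.
#' @param concurrency,cross_layer,sex_acts Passed to [model_params()].
#' @param keep_counts Keep the last replicate's per-node distinct-partner
#'   counts as the `counts` attribute of the returned summary (off by
#'   default: calibration only needs the quantile cells).
#' @return Function `f(theta)` returning a [partner_summary()] or `NULL`.
#' @export
make_network_simulator <- function(pop, edges, deg, days = 365,
                                   replicates = 2, concurrency = NULL,
                                   cross_layer = NULL, sex_acts = NULL,
                                   keep_counts = FALSE) {
  force(pop); force(edges); force(deg)
  n_la <- pop$n - pop$n_ha
  function(theta) {
    hl <- list()
    for (ly in .layers) {
      nm <- c(steady = "h_steady", casual = "h_casual",
              oneoff = "h_oneoff")[[ly]]
      d <- deg[[ly]]
      h_la <- tryCatch(
        la_homophily(mixing_inputs(pop$n_ha, n_la, d[["ha"]], d[["la"]],
                                   theta[[nm]])),
        error = function(e) NA_real_)
      if (is.na(h_la)) return(NULL)
      hl[[ly]] <- c(ha = unname(theta[[nm]]), la = h_la)
    }
    share <- lapply(deg, function(d)
      pop$n_ha * d[["ha"]] / (pop$n_ha * d[["ha"]] + n_la * d[["la"]]))
    params <- model_params(
      durations = list(steady = theta[["dur_steady"]],
                       casual_hh = theta[["dur_casual_hh"]],
                       casual_ll = theta[["dur_casual_ll"]],
                       casual_hl = theta[["dur_casual_hl"]],
                       oneoff = 1),
      homophily = hl, edges = edges, ha_end_share = share,
      concurrency = concurrency, cross_layer = cross_layer,
      sex_acts = sex_acts)
    acc <- NULL
    counts <- NULL
    for (r in seq_len(replicates)) {
      s <- measure_cumulative_partners(
        simulate_network(pop, params, days = days))
      if (keep_counts) counts <- attr(s, "counts")
      attr(s, "counts") <- NULL
      acc <- if (is.null(acc)) s else {
        stopifnot(all(acc$group == s$group), all(acc$type == s$type))
        acc$median <- acc$median + s$median
        acc$q1 <- acc$q1 + s$q1
        acc$q3 <- acc$q3 + s$q3
        acc
      }
    }
    acc$median <- acc$median / replicates
    acc$q1 <- acc$q1 / replicates
    acc$q3 <- acc$q3 / replicates
    if (keep_counts) attr(acc, "counts") <- counts
    acc
  }
}

#' Parameter-recovery experiment on synthetic targets
#'
#' Generates calibration targets by simulating the network at known
#' parameters, then runs the full ABC-SMC calibration against them. The
#' default configuration uses a 1000-node population with the PrEP-scenario
#' HA fraction and priors; the experiment's purpose is to check that the
#' posterior concentrates around the generating truth.
#'
#' @param truth Named vector of the seven generating parameters.
#' @param n_nodes Population size.
#' @param ha_fraction HA fraction of the model population.
#' @param deg Per-layer per-group mean degrees of the synthetic population.
#' @param n_particles,alpha,p_acc_min,max_gen ABC-SMC controls.
#' @param days,replicates Simulation length and replicates per particle.
#' @param scenario Scenario providing the priors.
#' @param seed RNG seed.
#' @return List with `posterior` (`abc_posterior`), `summary`
#'   ([posterior_summary()]), `truth`, `target`.
#' @export
recovery_experiment <- function(truth = c(dur_steady = 1200,
                                          dur_casual_hh = 5,
                                          dur_casual_ll = 250,
                                          dur_casual_hl = 10,
                                          h_steady = 0.8, h_casual = 0.65,
                                          h_oneoff = 0.98),
                                n_nodes = 1000, ha_fraction = 0.346,
                                deg = list(steady = c(ha = 0.45, la = 0.30),
                                           casual = c(ha = 0.80, la = 0.28),
                                           oneoff = c(ha = 25 / 365,
                                                      la = 4 / 365)),
                                n_particles = 100, alpha = 0.5,
                                p_acc_min = 0.05, max_gen = 10,
                                days = 365, replicates = 2,
                                scenario = "prep_eligibility", seed = 1) {
  pop <- population(n_nodes, ha_fraction)
  n_la <- pop$n - pop$n_ha
  edges <- lapply(deg, function(d)
    (pop$n_ha * d[["ha"]] + n_la * d[["la"]]) / 2)
  simulator <- make_network_simulator(pop, edges, deg, days = days,
                                      replicates = replicates)
  set.seed(seed)
  target <- simulator(truth)
  if (is.null(target)) stop("generating truth is infeasible")
  post <- abc_smc(prior_spec(scenario), simulator, target,
                  n_particles = n_particles, alpha = alpha,
                  p_acc_min = p_acc_min, max_gen = max_gen,
                  seed = seed + 1)
  list(posterior = post, summary = posterior_summary(post), truth = truth,
       target = target)
}
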