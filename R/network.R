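#' Two-group model population
#'
#' @param n_nodes Number of individuals.
#' @param ha_fraction Fraction classified high-activity; the realised HA
#'   count is `round(n_nodes * ha_fraction)`.
#' @return Object of class `population`: list with `n`, `n_ha`, `group`
#'   (integer vector, 1 = HA, 2 = LA) and `members` (index list).
#' @export
population <- function(n_nodes, ha_fraction) {
  stopifnot(n_nodes > 0, ha_fraction >= 0, ha_fraction <= 1)
  n_ha <- round(n_nodes * ha_fraction)
  group <- c(rep.int(1L, n_ha), rep.int(2L, n_nodes - n_ha))
  structure(list(n = as.integer(n_nodes), n_ha = as.integer(n_ha),
                 ha_fraction = ha_fraction, group = group,
                 members = list(HA = which(group == 1L),
                                LA = which(group == 2L))),
            class = "population")
}

.layers <- c("steady", "casual", "oneoff")
.pair_types <- c("HH", "LL", "HL")

# round a non-negative real vector to integers preserving the rounded sum
.round_lr <- function(x) {
  f <- floor(x)
  r <- x - f
  k <- round(sum(x)) - sum(f)
  if (k > 0) {
    idx <- order(r, decreasing = TRUE)[seq_len(k)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

#' Model parameters for the three-layer partnership network
#'
#' Bundles dissolution, formation and sex-act parameters. Formation is
#' target-driven: each layer holds a target edge count split across the
#' group pairs HA-HA, LA-LA and HA-LA ([pair_mix()]) so that both groups'
#' homophily rates sit at their targets in expectation. Steady and casual
#' partnerships dissolve with constant daily hazard `1/duration` (the steady
#' hazard is common to all group pairs, the casual hazard is keyed on the
#' unordered pair); one-off partnerships always last exactly one day, so the
#' one-off "edge count" is the expected number of new one-off partnerships
#' per day.
#'
#' @param durations List with `steady`, `casual_hh`, `casual_ll`,
#'   `casual_hl` mean durations in days (>= 1) and `oneoff` (must be 1).
#' @param homophily List with elements `steady`, `casual`, `oneoff`, each a
#'   vector `c(ha =, la =)` of homophily rates.
#' @param edges List with target edge counts `steady`, `casual` and the
#'   daily one-off formation target `oneoff`.
#' @param ha_end_share Optional list of fallback HA end shares per layer for
#'   the degenerate no-cross-edge case (default 0.5 each).
#' @param concurrency Optional list of per-layer target distributions over
#'   the momentary degree classes 0/1/>1 (numeric length-3, summing to 1);
#'   `NULL` disables concurrency control for that layer.
#' @param concurrency_band Tolerance band around the concurrency targets
#'   (fraction of nodes, default 0.02).
#' @param cross_layer Optional list of formation weights by the candidate's
#'   degree class (0/1/>1) in the other layer: elements `steady` (weights by
#'   casual class), `casual` (by steady class) and `oneoff` (list with
#'   `steady` and `casual` weight vectors). Default neutral (all 1).
#' @param sex_acts Optional [sex_act_params()]; `NULL` disables sex-act
#'   simulation.
#' @return Object of class `model_params`.
#' @export
model_params <- function(durations = list(steady = 1200, casual_hh = 5,
                                          casual_ll = 250, casual_hl = 10,
                                          oneoff = 1),
                         homophily = list(steady = c(ha = 0.8, la = 0.9),
                                          casual = c(ha = 0.65, la = 0.5),
                                          oneoff = c(ha = 0.98, la = 0.95)),
                         edges = list(steady = 175, casual = 230,
                                      oneoff = 15),
                         ha_end_share = NULL,
                         concurrency = NULL,
                         concurrency_band = 0.02,
                         cross_layer = NULL,
                         sex_acts = NULL) {
  need <- c("steady", "casual_hh", "casual_ll", "casual_hl")
  stopifnot(all(need %in% names(durations)),
            all(unlist(durations[need]) >= 1))
  if (is.null(durations$oneoff)) durations$oneoff <- 1
  if (durations$oneoff != 1)
    stop("one-off partnerships last exactly 1 day")
  for (ly in .layers) {
    h <- homophily[[ly]]
    stopifnot(length(h) == 2, all(h >= 0), all(h <= 1))
  }
  if (is.null(ha_end_share))
    ha_end_share <- list(steady = 0.5, casual = 0.5, oneoff = 0.5)
  hazards <- list(
    steady = rep(duration_to_hazard(durations$steady), 3),
    casual = duration_to_hazard(c(durations$casual_hh, durations$casual_ll,
                                  durations$casual_hl)),
    oneoff = rep(1, 3))
  counts <- lapply(.layers, function(ly) {
    h <- homophily[[ly]]
    pair_mix(edges[[ly]], h[["ha"]], h[["la"]], ha_end_share[[ly]])
  })
  names(counts) <- .layers
  if (!is.null(cross_layer)) {
    for (nm in c("steady", "casual"))
      if (!is.null(cross_layer[[nm]]))
        stopifnot(length(cross_layer[[nm]]) == 3,
                  all(cross_layer[[nm]] >= 0))
  }
  structure(list(durations = durations, homophily = homophily,
                 edges = edges, counts = counts,
                 counts_int = lapply(counts, .round_lr),
                 hazards = hazards,
                 concurrency = concurrency,
                 concurrency_band = concurrency_band,
                 cross_layer = cross_layer,
                 sex_acts = sex_acts),
            class = "model_params")
}

#' Daily sex-act parameters
#'
#' Each surviving partnership has one sex act per day with a Bernoulli
#' probability depending on layer and group pair; each act is assigned a
#' combination of the six sex types (oral, oro-anal and anal, each insertive
#' or receptive) from a frequency table. The default frequencies are a
#' synthetic stand-in.
#'
#' @param prob 3x3 matrix of daily act probabilities, rows = layers
#'   (steady, casual, oneoff), columns = group pairs (HH, LL, HL).
#' @param combos Data frame with columns `combo` (character, "+"-separated
#'   sex-type labels) and `prob` (frequencies summing to 1).
#' @return Object of class `sex_act_params`.
#' @export
sex_act_params <- function(prob = matrix(c(0.35, 0.35, 0.35,
                                           0.25, 0.25, 0.25,
                                           1.00, 1.00, 1.00),
                                         nrow = 3, byrow = TRUE,
                                         dimnames = list(.layers,
                                                         .pair_types)),
                           combos = data.frame(
                             combo = c("oral_i+oral_r",
                                       "oral_i+oral_r+anal_i",
                                       "oral_i+oral_r+anal_r",
                                       "anal_i", "anal_r",
                                       "oral_i", "oral_r",
                                       "oral_i+oroanal_i",
                                       "oral_r+oroanal_r",
                                       "oral_i+oral_r+oroanal_i+oroanal_r+anal_i+anal_r"),
                             prob = c(0.22, 0.16, 0.16, 0.08, 0.08,
                                      0.08, 0.08, 0.05, 0.05, 0.04),
                             stringsAsFactors = FALSE)) {
  stopifnot(all(prob >= 0), all(prob <= 1),
            abs(sum(combos$prob) - 1) < 1e-8, all(combos$prob >= 0))
  structure(list(prob = prob, combos = combos), class = "sex_act_params")
}

.empty_layer <- function() {
  list(i = integer(0), j = integer(0), type = integer(0), age = integer(0),
       log_row = integer(0))
}

.new_log <- function(cap = 256L) {
  list(mat = matrix(NA_integer_, nrow = cap, ncol = 5,
                    dimnames = list(NULL, c("i", "j", "type", "formed",
                                            "died"))),
       n = 0L)
}

.log_append <- function(log, i, j, type, formed, died = -1L) {
  k <- length(i)
  if (k == 0) return(list(log = log, rows = integer(0)))
  while (log$n + k > nrow(log$mat)) {
    log$mat <- rbind(log$mat,
                     matrix(NA_integer_, nrow = nrow(log$mat), ncol = 5))
  }
  rows <- log$n + seq_len(k)
  log$mat[rows, 1L] <- i
  log$mat[rows, 2L] <- j
  log$mat[rows, 3L] <- type
  log$mat[rows, 4L] <- formed
  log$mat[rows, 5L] <- died
  log$n <- log$n + k
  list(log = log, rows = rows)
}

# degree class (0, 1, >1) helper
.deg_class <- function(deg) pmin(deg, 2L)

# candidate selection weights from cross-layer status mix
.xlayer_weights <- function(state, layer, params) {
  cl <- params$cross_layer
  if (is.null(cl)) return(NULL)
  w <- rep(1, state$pop$n)
  if (layer == "steady" && !is.null(cl$steady))
    w <- w * cl$steady[.deg_class(state$deg$casual) + 1L]
  if (layer == "casual" && !is.null(cl$casual))
    w <- w * cl$casual[.deg_class(state$deg$steady) + 1L]
  if (layer == "oneoff" && !is.null(cl$oneoff)) {
    if (!is.null(cl$oneoff$steady))
      w <- w * cl$oneoff$steady[.deg_class(state$deg$steady) + 1L]
    if (!is.null(cl$oneoff$casual))
      w <- w * cl$oneoff$casual[.deg_class(state$deg$casual) + 1L]
  }
  if (all(w == w[1])) NULL else w
}

# Draw k new partnerships of a given group-pair type for one layer.
# Candidates violating the no-self-loop / no-duplicate rules, or pushing the
# layer's degree-class distribution outside the concurrency tolerance band,
# are redrawn for up to ten rounds and then accepted (degenerate targets
# must not deadlock formation).
.draw_pairs <- function(state, layer, type, k, params) {
  if (k <= 0) return(cbind(i = integer(0), j = integer(0)))
  pop <- state$pop
  w_all <- .xlayer_weights(state, layer, params)
  pools <- switch(.pair_types[type],
                  HH = list(pop$members$HA, pop$members$HA),
                  LL = list(pop$members$LA, pop$members$LA),
                  HL = list(pop$members$HA, pop$members$LA))
  pick <- function(pool, m) {
    if (length(pool) == 1) return(rep.int(pool, m))
    w <- if (is.null(w_all)) NULL else w_all[pool]
    pool[sample.int(length(pool), m, replace = TRUE, prob = w)]
  }
  deg <- state$deg[[layer]]
  conc <- params$concurrency[[layer]]
  band <- params$concurrency_band
  n <- pop$n
  frac2 <- sum(deg > 1L) / n
  frac0 <- sum(deg == 0L) / n
  ekey <- (pmin(state$edges[[layer]]$i, state$edges[[layer]]$j) - 1) * n +
    pmax(state$edges[[layer]]$i, state$edges[[layer]]$j)

  out_i <- integer(0); out_j <- integer(0)
  todo <- k
  for (round in 1:10) {
    i <- pick(pools[[1]], todo)
    j <- pick(pools[[2]], todo)
    key <- (pmin(i, j) - 1) * n + pmax(i, j)
    bad <- i == j | key %in% ekey | duplicated(key)
    if (!is.null(conc)) {
      push2 <- deg[i] >= 1L | deg[j] >= 1L
      leave0 <- deg[i] == 0L | deg[j] == 0L
      bad <- bad | (push2 & frac2 >= conc[3] + band) |
        (leave0 & frac0 <= conc[1] - band)
    }
    ok <- !bad
    out_i <- c(out_i, i[ok]); out_j <- c(out_j, j[ok])
    ekey <- c(ekey, key[ok])
    todo <- sum(bad)
    if (todo == 0) break
    if (round == 10) { # forced accept, minus hard violations
      hard <- i[bad] == j[bad] | key[bad] %in% ekey[seq_len(length(ekey))]
      out_i <- c(out_i, i[bad][!hard]); out_j <- c(out_j, j[bad][!hard])
    } else {
      i <- i[bad]; j <- j[bad]
    }
  }
  cbind(i = out_i, j = out_j)
}

.add_edges <- function(state, layer, pairs, type, age = NULL) {
  k <- nrow(pairs)
  if (k == 0) return(state)
  ap <- .log_append(state$log[[layer]], pairs[, "i"], pairs[, "j"],
                    rep.int(type, k), rep.int(state$day, k))
  state$log[[layer]] <- ap$log
  e <- state$edges[[layer]]
  e$i <- c(e$i, pairs[, "i"])
  e$j <- c(e$j, pairs[, "j"])
  e$type <- c(e$type, rep.int(as.integer(type), k))
  e$age <- c(e$age, if (is.null(age)) rep.int(0L, k) else as.integer(age))
  e$log_row <- c(e$log_row, ap$rows)
  state$edges[[layer]] <- e
  d <- state$deg[[layer]]
  tab <- tabulate(c(pairs[, "i"], pairs[, "j"]), nbins = state$pop$n)
  state$deg[[layer]] <- d + tab
  state
}

#' Initialise the network at its stationary targets
#'
#' Seeds the steady and casual layers at their target edge counts with the
#' group-pair composition implied by the homophily targets, and draws edge
#' ages from the geometric stationary age distribution (memorylessness makes
#' age and residual lifetime independent), so a measurement window can start
#' immediately in equilibrium. The one-off layer starts empty and is formed
#' day by day.
#'
#' @param pop A [population()].
#' @param params A [model_params()].
#' @return Object of class `network_state`.
#' @export
initialize_state <- function(pop, params) {
  stopifnot(inherits(pop, "population"), inherits(params, "model_params"))
  cap_hh <- choose(pop$n_ha, 2)
  cap_ll <- choose(pop$n - pop$n_ha, 2)
  cap_hl <- pop$n_ha * (pop$n - pop$n_ha)
  for (ly in c("steady", "casual")) {
    ci <- params$counts_int[[ly]]
    if (ci[1] > cap_hh || ci[2] > cap_ll || ci[3] > cap_hl)
      stop("infeasible targets: layer ", ly,
           " edge counts exceed group capacity")
  }
  state <- list(day = 0L, pop = pop,
                edges = list(steady = .empty_layer(),
                             casual = .empty_layer(),
                             oneoff = .empty_layer()),
                deg = list(steady = integer(pop$n),
                           casual = integer(pop$n),
                           oneoff = integer(pop$n)),
                log = list(steady = .new_log(), casual = .new_log(),
                           oneoff = .new_log(1024L)),
                acts = NULL)
  if (!is.null(params$sex_acts))
    state$acts <- stats::setNames(
      numeric(nrow(params$sex_acts$combos)), params$sex_acts$combos$combo)
  for (ly in c("steady", "casual")) {
    ci <- params$counts_int[[ly]]
    for (t in 1:3) {
      if (ci[t] == 0) next
      pairs <- .draw_pairs(state, ly, t, ci[t], params)
      ages <- stats::rgeom(nrow(pairs), params$hazards[[ly]][t])
      state <- .add_edges(state, ly, pairs, t, age = ages)
    }
  }
  class(state) <- "network_state"
  state
}

#' Advance the network by one day
#'
#' In order: (1) dissolution -- every steady/casual partnership ends with
#' its layer/group-pair daily hazard, every one-off partnership ends;
#' (2) surviving partnerships age by one day; (3) formation -- each layer's
#' group-pair edge counts are topped back up to their targets (the expected
#' number of new edges per day equals target x hazard, the equilibrium
#' identity), with endpoints drawn under the concurrency band and
#' cross-layer weights; the one-off layer forms a Poisson number of new
#' partnerships around its daily target; (4) sex acts -- each surviving
#' partnership has a Bernoulli sex act, assigned a sex-type combination from
#' the frequency table.
#'
#' @param state A `network_state`.
#' @param params A [model_params()].
#' @return The updated `network_state`.
#' @export
step <- function(state, params) {
  state$day <- state$day + 1L
  # (1) dissolution + (2) ageing
  for (ly in .layers) {
    e <- state$edges[[ly]]
    ne <- length(e$i)
    if (ne == 0) next
    haz <- params$hazards[[ly]][e$type]
    died <- if (ly == "oneoff") rep.int(TRUE, ne)
            else stats::runif(ne) < haz
    if (any(died)) {
      rows <- e$log_row[died]
      # last day alive: one-off partnerships live exactly their formation day
      state$log[[ly]]$mat[rows, "died"] <-
        if (ly == "oneoff") state$log[[ly]]$mat[rows, "formed"]
        else state$day
      tab <- tabulate(c(e$i[died], e$j[died]), nbins = state$pop$n)
      state$deg[[ly]] <- state$deg[[ly]] - tab
      keep <- !died
      e <- lapply(e, function(v) v[keep])
    }
    e$age <- e$age + 1L
    state$edges[[ly]] <- e
  }
  # (3) formation
  for (ly in c("steady", "casual")) {
    current <- tabulate(state$edges[[ly]]$type, nbins = 3)
    deficit <- params$counts_int[[ly]] - current
    for (t in 1:3) {
      if (deficit[t] <= 0) next
      pairs <- .draw_pairs(state, ly, t, deficit[t], params)
      state <- .add_edges(state, ly, pairs, t)
    }
  }
  for (t in 1:3) {
    rate <- params$counts[["oneoff"]][t]
    if (rate <= 0) next
    k <- stats::rpois(1, rate)
    if (k == 0) next
    pairs <- .draw_pairs(state, "oneoff", t, k, params)
    if (is.null(params$sex_acts)) {
      # one-off partnerships live exactly one day: without sex acts they can
      # be closed in the log immediately and skip the live edge set
      ap <- .log_append(state$log$oneoff, pairs[, "i"], pairs[, "j"],
                        rep.int(t, nrow(pairs)), rep.int(state$day,
                                                         nrow(pairs)),
                        died = state$day)
      state$log$oneoff <- ap$log
    } else {
      state <- .add_edges(state, "oneoff", pairs, t)
    }
  }
  # (4) sex acts
  sa <- params$sex_acts
  if (!is.null(sa)) {
    for (ly in .layers) {
      e <- state$edges[[ly]]
      ne <- length(e$i)
      if (ne == 0) next
      p <- sa$prob[ly, e$type]
      acts <- stats::runif(ne) < p
      na <- sum(acts)
      if (na > 0) {
        combo <- sample.int(nrow(sa$combos), na, replace = TRUE,
                            prob = sa$combos$prob)
        tab <- tabulate(combo, nbins = nrow(sa$combos))
        state$acts <- state$acts + tab
      }
    }
  }
  state
}

#' Simulate the three-layer network over a number of days
#'
#' Initialises at the stationary targets and runs daily steps, keeping a log
#' of every partnership's formation and dissolution day.
#'
#' @inheritParams initialize_state
#' @param days Number of daily steps (e.g. 365 for a 12-month window).
#' @param seed Optional RNG seed.
#' @return Object of class `msm_sim`: list with the final `state`, `pop`,
#'   `params` and `days`.
#' @export
simulate_network <- function(pop, params, days = 365, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- initialize_state(pop, params)
  for (d in seq_len(days)) state <- step(state, params)
  structure(list(state = state, pop = pop, params = params, days = days),
            class = "msm_sim")
}

#' Cumulative distinct partners per node over a window
#'
#' Counts, for every node and layer, the number of distinct partners with
#' whom a partnership was active at any point during the final `window` days
#' of the simulation (a re-formed partnership with the same partner counts
#' once), and summarises the counts per activity group with the
#' linear-interpolation quantile convention shared with the survey targets.
#'
#' @param sim An `msm_sim` from [simulate_network()].
#' @param window Window length in days; defaults to the full simulated span.
#' @return A [partner_summary()] with attribute `counts` (per-layer list of
#'   per-node distinct-partner counts).
#' @export
measure_cumulative_partners <- function(sim, window = NULL) {
  stopifnot(inherits(sim, "msm_sim"))
  if (is.null(window)) window <- sim$days
  if (window > sim$days) stop("window longer than simulated history")
  start <- sim$days - window + 1L
  n <- sim$pop$n
  counts <- list()
  for (ly in .layers) {
    log <- sim$state$log[[ly]]
    m <- log$mat[seq_len(log$n), , drop = FALSE]
    if (nrow(m) > 0) {
      active <- m[, "formed"] <= sim$days &
        (m[, "died"] == -1L | m[, "died"] >= start)
      m <- m[active, , drop = FALSE]
    }
    if (nrow(m) == 0) {
      counts[[ly]] <- integer(n)
      next
    }
    key <- (pmin(m[, "i"], m[, "j"]) - 1) * n + pmax(m[, "i"], m[, "j"])
    keep <- !duplicated(key)
    counts[[ly]] <- tabulate(c(m[keep, "i"], m[keep, "j"]), nbins = n)
  }
  grp <- ifelse(sim$pop$group == 1L, "HA", "LA")
  out <- expand.grid(group = c("HA", "LA"), type = .layers,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$median <- out$q1 <- out$q3 <- NA_real_
  for (r in seq_len(nrow(out))) {
    v <- counts[[out$type[r]]][grp == out$group[r]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    out$q1[r] <- q[1]; out$median[r] <- q[2]; out$q3[r] <- q[3]
  }
  res <- partner_summary(out)
  attr(res, "counts") <- counts
  res
}

#' Cross-group partnership tallies from each side
#'
#' Counts HA-LA partnerships in a layer once from the HA side and once from
#' the LA side; mixing balance requires the two tallies to agree exactly.
#'
#' @param state A `network_state`.
#' @param layer Layer name.
#' @return Named integer vector `c(from_ha =, from_la =)`.
#' @export
cross_group_tally <- function(state, layer = "steady") {
  e <- state$edges[[layer]]
  g <- state$pop$group
  cross <- g[e$i] != g[e$j]
  c(from_ha = sum((g[e$i] == 1L & cross) | (g[e$j] == 1L & cross)),
    from_la = sum((g[e$i] == 2L & cross) | (g[e$j] == 2L & cross)))
}

#' Derive formation targets and mixing degrees from a reconstructed survey
#'
#' Converts survey-level information into the simulator's scale: per-group
#' momentary mean degrees for the steady and casual layers from the
#' ongoing-partnership status (0/1/>1 read as 0, 1, 2), a per-group daily
#' one-off rate from the reconstructed yearly one-off counts, layer edge
#'-count targets for a model population of `n_nodes`, and the concurrency
#' target distributions.
#'
#' @param survey An `msm_survey`.
#' @param recon A `recon_result` from [reconstruct_survey()].
#' @param groups Character vector of "HA"/"LA" labels per respondent.
#' @param n_nodes Model population size.
#' @return List with `ha_fraction`, `edges`, `deg` (per-layer `c(ha =, la =)`
#'   mean degrees), and `concurrency`.
#' @export
formation_targets_from_survey <- function(survey, recon, groups, n_nodes) {
  stopifnot(nrow(survey) == length(groups),
            nrow(recon$counts) == length(groups))
  ha <- groups == "HA"
  f_ha <- mean(ha)
  n_ha <- round(n_nodes * f_ha); n_la <- n_nodes - n_ha
  ord_deg <- function(x) mean(c("0" = 0, "1" = 1, ">1" = 2)[x])
  deg <- list(
    steady = c(ha = ord_deg(survey$ongoing_steady[ha]),
               la = ord_deg(survey$ongoing_steady[!ha])),
    casual = c(ha = ord_deg(survey$ongoing_casual[ha]),
               la = ord_deg(survey$ongoing_casual[!ha])),
    oneoff = c(ha = mean(recon$counts$one_off[ha]) / 365,
               la = mean(recon$counts$one_off[!ha]) / 365))
  edges <- lapply(deg, function(d)
    (n_ha * d[["ha"]] + n_la * d[["la"]]) / 2)
  conc <- function(x) {
    p <- table(factor(x, levels = c("0", "1", ">1"))) / length(x)
    as.numeric(p)
  }
  list(ha_fraction = f_ha, edges = edges, deg = deg,
       concurrency = list(steady = conc(survey$ongoing_steady),
                          casual = conc(survey$ongoing_casual),
                          oneoff = NULL))
}
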