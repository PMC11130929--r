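test_that("durations convert to daily hazards", {
  expect_equal(duration_to_hazard(1), 1)
  expect_equal(duration_to_hazard(251), 1 / 251)
  expect_equal(duration_to_hazard(1409), 1 / 1409)
  expect_error(duration_to_hazard(0.5), "at least 1")
})

test_that("the Weibull mean matches numerical integration", {
  for (p in list(c(0.61, 920), c(1, 100), c(2, 50))) {
    closed <- weibull_mean_duration(p[1], p[2])
    numeric <- stats::integrate(function(t)
      stats::pweibull(t, p[1], p[2], lower.tail = FALSE),
      0, Inf, rel.tol = 1e-9)$value
    expect_equal(closed, numeric, tolerance = 1e-6)
  }
})

test_that("simulated lifetimes are geometric with the configured mean", {
  set.seed(41)
  life <- simulate_edge_lifetimes(2e4, 13)
  expect_lt(abs(mean(life) - 13) / 13, 0.05)
  expect_true(all(simulate_edge_lifetimes(100, 1) == 1))
})

test_that("dissolution is memoryless: hazard flat in edge age", {
  set.seed(42)
  life <- simulate_edge_lifetimes(2e4, 20)
  # deaths by age bin vs geometric expectation
  bins <- 1:12
  at_risk <- vapply(bins, function(a) sum(life >= a), numeric(1))
  deaths <- vapply(bins, function(a) sum(life == a), numeric(1))
  # conditional death probability should be 1/20 at every age
  cs <- suppressWarnings(stats::chisq.test(
    cbind(deaths, at_risk - deaths)))
  expect_gt(cs$p.value, 0.01)
})

test_that("initialisation hits targets, mixing and stationary ages", {
  fm <- fx_model(n = 1000)
  st <- initialize_state(fm$pop, fm$params)
  for (ly in c("steady", "casual"))
    expect_equal(length(st$edges[[ly]]$i),
                 sum(fm$params$counts_int[[ly]]))
  expect_equal(length(st$edges$oneoff$i), 0)
  # realised HA concordance equals the integer-rounded target mix
  e <- st$edges$casual
  tab <- tabulate(e$type, 3)
  h_real <- 2 * tab[1] / (2 * tab[1] + tab[3])
  expect_lt(abs(h_real - 0.65), 0.02)
  expect_true(all(e$i != e$j))
  key <- pmin(e$i, e$j) * 1e6 + pmax(e$i, e$j)
  expect_false(any(duplicated(key)))
  # stationary ages: mean age of casual HH edges ~ D_HH (geometric)
  hh_age <- st$edges$casual$age[e$type == 1]
  expect_lt(abs(mean(hh_age) - 5) / 5, 0.5)
})

test_that("degenerate targets give an empty or emptying network", {
  pop <- population(100, 0.3)
  p0 <- model_params(edges = list(steady = 0, casual = 0, oneoff = 0))
  st <- initialize_state(pop, p0)
  expect_equal(sum(vapply(st$edges, function(e) length(e$i), numeric(1))), 0)
  # hazard 1 everywhere with zero formation empties the network in one step
  p1 <- model_params(durations = list(steady = 1, casual_hh = 1,
                                      casual_ll = 1, casual_hl = 1,
                                      oneoff = 1),
                     edges = list(steady = 20, casual = 20, oneoff = 0))
  st <- initialize_state(pop, p1)
  p1$counts_int <- lapply(p1$counts_int, function(x) x * 0L)
  st <- step(st, p1)
  expect_equal(sum(vapply(st$edges, function(e) length(e$i), numeric(1))), 0)
})

test_that("fully assortative homophily yields no cross-group edges", {
  fm <- fx_model(n = 400, h = c(steady = 1, casual = 1, oneoff = 1))
  st <- initialize_state(fm$pop, fm$params)
  g <- fm$pop$group
  for (ly in c("steady", "casual")) {
    e <- st$edges[[ly]]
    expect_true(all(g[e$i] == g[e$j]))
  }
})

test_that("edge counts stay at target through time (birth-death balance)", {
  set.seed(7)
  fm <- fx_model(n = 300, durations = list(steady = 50, casual_hh = 5,
                                           casual_ll = 40, casual_hl = 10,
                                           oneoff = 1))
  st <- initialize_state(fm$pop, fm$params)
  tot <- c(steady = 0, casual = 0)
  nsteps <- 600
  for (k in seq_len(nsteps)) {
    st <- step(st, fm$params)
    tot["steady"] <- tot["steady"] + length(st$edges$steady$i)
    tot["casual"] <- tot["casual"] + length(st$edges$casual$i)
  }
  for (ly in c("steady", "casual")) {
    target <- sum(fm$params$counts_int[[ly]])
    expect_lt(abs(tot[[ly]] / nsteps - target) / target, 0.05)
  }
})

test_that("one-off accumulation matches its formation rate", {
  set.seed(8)
  fm <- fx_model(n = 500)
  sim <- simulate_network(fm$pop, fm$params, days = 365)
  m <- measure_cumulative_partners(sim)
  counts <- attr(m, "counts")
  expected_per_node <- 2 * sum(fm$params$counts$oneoff) * 365 / fm$pop$n
  expect_lt(abs(mean(counts$oneoff) - expected_per_node) /
              expected_per_node, 0.1)
})

test_that("cumulative casual partners follow the renewal approximation", {
  # one group, one duration: per-node mean ~ degree * (1 + 365/D)
  set.seed(9)
  pop <- population(2000, 0.5)
  params <- model_params(
    durations = list(steady = 1000, casual_hh = 251, casual_ll = 251,
                     casual_hl = 251, oneoff = 1),
    homophily = list(steady = c(ha = 1, la = 1),
                     casual = c(ha = 0.5, la = 0.5),
                     oneoff = c(ha = 0.5, la = 0.5)),
    edges = list(steady = 0, casual = 500, oneoff = 0))
  sim <- simulate_network(pop, params, days = 365)
  counts <- attr(measure_cumulative_partners(sim), "counts")
  expected <- 0.5 * (1 + 365 / 251)
  expect_lt(abs(mean(counts$casual) - expected) / expected, 0.1)
})

test_that("cross-group tallies balance exactly at every step", {
  set.seed(10)
  fm <- fx_model(n = 300)
  st <- initialize_state(fm$pop, fm$params)
  for (k in 1:25) {
    st <- step(st, fm$params)
    for (ly in c("steady", "casual")) {
      ct <- cross_group_tally(st, ly)
      expect_identical(ct[["from_ha"]], ct[["from_la"]])
    }
  }
})

test_that("one-off edges never age and vanish each day", {
  fm <- fx_model(n = 200, sex_acts = sex_act_params())
  set.seed(12)
  st <- initialize_state(fm$pop, fm$params)
  for (k in 1:10) {
    st <- step(st, fm$params)
    expect_true(all(st$edges$oneoff$age == 0L))
  }
  # every logged one-off partnership lived exactly one day
  log <- st$log$oneoff
  m <- log$mat[seq_len(log$n), , drop = FALSE]
  done <- m[, "died"] != -1L
  expect_true(all(m[done, "died"] == m[done, "formed"]))
})

test_that("sex acts are drawn and assigned to type combinations", {
  fm <- fx_model(n = 200, sex_acts = sex_act_params())
  sim <- simulate_network(fm$pop, fm$params, days = 30, seed = 13)
  acts <- sim$state$acts
  expect_true(sum(acts) > 0)
  expect_named(acts, sex_act_params()$combos$combo)
})

test_that("simulation is reproducible and the window is validated", {
  fm <- fx_model(n = 200)
  a <- simulate_network(fm$pop, fm$params, days = 60, seed = 99)
  b <- simulate_network(fm$pop, fm$params, days = 60, seed = 99)
  expect_identical(a$state$log, b$state$log)
  expect_identical(as.data.frame(measure_cumulative_partners(a)),
                   as.data.frame(measure_cumulative_partners(b)))
  expect_error(measure_cumulative_partners(a, window = 100), "window")
})

test_that("infeasible edge targets are rejected at initialisation", {
  pop <- population(20, 0.5)
  # 100 HA-HA steady edges cannot fit among choose(10, 2) = 45 HA pairs
  params <- model_params(edges = list(steady = 200, casual = 0, oneoff = 0),
                         homophily = list(steady = c(ha = 1, la = 1),
                                          casual = c(ha = 0.5, la = 0.5),
                                          oneoff = c(ha = 0.5, la = 0.5)))
  expect_error(initialize_state(pop, params), "infeasible")
})

test_that("survey-derived formation targets have the right scale", {
  sv <- fx_survey("prep_eligibility")
  rec <- fx_recon("prep_eligibility")
  groups <- classify_activity(sv, "prep_eligibility")
  base <- formation_targets_from_survey(sv, rec, groups, 1000)
  expect_equal(base$ha_fraction, mean(groups == "HA"))
  for (ly in c("steady", "casual", "oneoff")) {
    d <- base$deg[[ly]]
    expect_equal(unname(base$edges[[ly]]),
                 (round(1000 * base$ha_fraction) * d[["ha"]] +
                    (1000 - round(1000 * base$ha_fraction)) * d[["la"]]) / 2)
  }
  expect_equal(sum(base$concurrency$casual), 1)
})
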