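mk_summary <- function(v) {
  partner_summary(data.frame(group = "HA", type = "steady",
                             median = v, q1 = v, q3 = v))
}

toy_prior <- function(lower = 0, upper = 20) {
  structure(data.frame(name = "x", lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("prior_spec", "data.frame"))
}

test_that("the summary distance is a normalised L1 over cells", {
  a <- mk_summary(10)
  expect_equal(summary_distance(a, a), 0)
  expect_equal(summary_distance(mk_summary(10), mk_summary(5)), 3 * 1)
  b <- data.frame(group = c("HA", "LA"), type = "casual",
                  median = c(10, 3), q1 = c(8, 2), q3 = c(12, 4))
  b <- partner_summary(b)
  expect_equal(summary_distance(b[2:1, ], b), 0) # order-invariant
  expect_error(summary_distance(a, b), "cells")
})

test_that("weighted quantiles ignore zero-weight particles", {
  expect_equal(weighted_quantile(c(1, 2, 3), c(0, 0, 1), c(0.025, 0.975)),
               c(3, 3))
  expect_equal(weighted_quantile(c(1, 2, 3), c(1, 1, 1), 0.5), 2)
})

test_that("prior bounds follow the scenario definitions", {
  pr <- prior_spec("prep_eligibility")
  expect_equal(pr$lower[pr$name == "dur_casual_hh"], 4)
  expect_equal(pr$upper[pr$name == "dur_casual_hh"], 15)
  pr2 <- prior_spec("gt15_total")
  expect_equal(pr2$lower[pr2$name == "h_casual"], 0.60)
  expect_equal(pr2$lower[pr2$name == "dur_casual_hl"], 5)
  pr3 <- prior_spec("gt15_casual", override = list(dur_steady = c(900, 1100)))
  expect_equal(pr3$lower[pr3$name == "dur_steady"], 900)
})

test_that("a perfectly fitting simulator leaves the prior untouched", {
  target <- mk_summary(7)
  post <- abc_smc(toy_prior(), function(theta) target, target,
                  n_particles = 100, max_gen = 3, seed = 8)
  s <- posterior_summary(post)
  expect_lt(abs(s$mean - 10), 2) # prior mean of U(0, 20)
  expect_gt(s$ci_high - s$ci_low, 10) # no spurious concentration
})

test_that("a known truth is recovered on a toy model", {
  set.seed(14)
  simulator <- function(theta) mk_summary(theta[["x"]] + rnorm(1, 0, 0.5))
  post <- abc_smc(toy_prior(), simulator, mk_summary(7),
                  n_particles = 100, max_gen = 8, seed = 15)
  s <- posterior_summary(post)
  expect_lt(abs(s$mean - 7), 0.5)
  expect_true(s$ci_low <= 7 && 7 <= s$ci_high)
  # brute-force rejection ABC as an independent oracle
  th <- runif(3e4, 0, 20)
  d <- abs(th + rnorm(3e4, 0, 0.5) - 7)
  oracle <- mean(th[rank(d) <= 300])
  expect_lt(abs(s$mean - oracle), 0.6)
})

test_that("posterior invariants hold", {
  simulator <- function(theta) mk_summary(theta[["x"]] + rnorm(1, 0, 1))
  post <- abc_smc(toy_prior(), simulator, mk_summary(12),
                  n_particles = 60, max_gen = 4, seed = 20)
  expect_true(all(diff(post$eps_trace) <= 1e-12))
  expect_equal(sum(post$weights), 1)
  s <- posterior_summary(post)
  expect_true(s$mean >= 0 && s$mean <= 20)
  expect_true(s$ci_low <= s$mean && s$mean <= s$ci_high)
  post2 <- abc_smc(toy_prior(), simulator, mk_summary(12),
                   n_particles = 60, max_gen = 4, seed = 20)
  expect_identical(post$particles, post2$particles)
})

test_that("simulator failures abort with the offending parameters", {
  boom <- function(theta) stop("network exploded")
  expect_error(abc_smc(toy_prior(), boom, mk_summary(1), n_particles = 10,
                       seed = 1),
               "x=.*network exploded")
  # NULL means infeasible: treated as infinite distance, not an error
  half <- function(theta)
    if (theta[["x"]] > 10) NULL else mk_summary(theta[["x"]])
  post <- abc_smc(toy_prior(), half, mk_summary(5), n_particles = 30,
                  max_gen = 2, seed = 2)
  expect_true(all(post$particles[, "x"] <= 10))
})

test_that("the posterior table follows the published layout", {
  particles <- cbind(dur_steady = c(1000, 1200, 1400),
                     dur_casual_hh = c(5, 6, 7),
                     dur_casual_ll = c(200, 250, 300),
                     dur_casual_hl = c(10, 12, 14),
                     h_steady = c(0.7, 0.8, 0.9),
                     h_casual = c(0.6, 0.65, 0.7),
                     h_oneoff = c(0.9, 0.95, 0.99))
  post <- structure(list(particles = particles, weights = c(0, 0, 1),
                         distances = c(1, 1, 1),
                         priors = prior_spec("prep_eligibility")),
                    class = "abc_posterior")
  s <- posterior_summary(post)
  expect_equal(s$mean[s$name == "dur_steady"], 1400)
  expect_equal(s$ci_low[s$name == "dur_steady"], 1400)
  tab <- posterior_table(post, "prep_eligibility",
                         mixing = list(n_ha = 346, n_la = 654,
                                       deg = list(steady = c(ha = 0.45,
                                                             la = 0.30),
                                                  casual = c(ha = 0.8,
                                                             la = 0.28),
                                                  oneoff = c(ha = 0.07,
                                                             la = 0.011))))
  expect_equal(tab$parameter[1],
               "Average duration of steady partnerships (in days)")
  expect_equal(sum(tab$note == "Calculated from network"), 3)
  expect_equal(tab$prior[1], "Uniform (800, 2000)")
  # derived LA steady rate at the selected particle
  h_la <- la_homophily(mixing_inputs(346, 654, 0.45, 0.30, 0.9))
  expect_equal(tab$mean[tab$parameter == "Homophily rate, steady, LA-MSM"],
               h_la)
})

test_that("uniform-weight posteriors average plainly", {
  post <- structure(list(particles = cbind(x = c(1, 2, 3)),
                         weights = rep(1 / 3, 3), distances = rep(0, 3),
                         priors = toy_prior()),
                    class = "abc_posterior")
  expect_equal(posterior_summary(post)$mean, 2)
})
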