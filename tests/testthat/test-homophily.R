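test_that("balance is symmetric for equal groups and trivial at h = 1", {
  eq <- mixing_inputs(500, 500, 1.2, 1.2, 0.8)
  expect_equal(la_homophily(eq), 0.8)
  one <- mixing_inputs(300, 700, 2.0, 0.4, 1.0)
  expect_equal(la_homophily(one), 1.0)
})

test_that("derived LA rate matches an explicit mixing-matrix count", {
  # HA group smaller but more active (degree ratio 0.9 per person means the
  # HA side brings 346*0.9 = 311.4 partnership ends per unit LA degree)
  inp <- mixing_inputs(346, 654, 0.9, 1.0, 0.79)
  h_la <- la_homophily(inp)
  expect_equal(round(h_la, 2), 0.90)
  m <- mixing_matrix(inp)
  # cross-partnership conservation, to machine precision
  expect_equal(m["HA", "LA"], m["LA", "HA"], tolerance = 1e-12)
  # diagonal shares reproduce the homophily rates
  expect_equal(m["HA", "HA"] / sum(m["HA", ]), 0.79)
  expect_equal(m["LA", "LA"] / sum(m["LA", ]), h_la)
})

test_that("the balance equation round-trips and is monotone", {
  inp <- mixing_inputs(346, 654, 0.8, 0.28, 0.5)
  for (h in seq(0.45, 0.99, by = 0.06)) {
    inp$h_ha <- h
    expect_equal(ha_homophily(inp, la_homophily(inp)), h,
                 tolerance = 1e-12)
  }
  hs <- seq(0.45, 0.99, by = 0.02)
  hl <- vapply(hs, function(h) { inp$h_ha <- h; la_homophily(inp) },
               numeric(1))
  expect_true(all(diff(hl) > 0))
})

test_that("infeasible mixing is an error, not a silent clamp", {
  # a dominant HA side cannot have most partnerships cross-group
  inp <- mixing_inputs(900, 100, 2.0, 0.5, 0.2)
  expect_error(la_homophily(inp), "infeasible")
  expect_error(mixing_inputs(0, 100, 1, 1, 0.5))
  expect_error(la_homophily(mixing_inputs(10, 10, 1, 0, 0.5)), "positive")
})

test_that("pair-type mix realises both homophily targets", {
  mix <- pair_mix(230, 0.65, 0.4715)
  expect_equal(sum(mix), 230)
  expect_equal(2 * mix[["HH"]] / (2 * mix[["HH"]] + mix[["HL"]]), 0.65)
  expect_equal(2 * mix[["LL"]] / (2 * mix[["LL"]] + mix[["HL"]]), 0.4715)
  # no cross edges when either group is fully assortative
  expect_equal(unname(pair_mix(100, 1, 1, ha_end_share = 0.3)),
               c(30, 70, 0))
  expect_equal(unname(pair_mix(0, 0.5, 0.5)), c(0, 0, 0))
})
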