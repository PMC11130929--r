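test_that("total-category resolution follows the overlap rule", {
  # steady 2 + casual 11-20: totals 13..22 overlap 11-20 on 8 of 10 integers
  set.seed(1)
  r <- resolve_total_category(2, "11-20")
  expect_equal(unname(r$prob["11-20"]), 0.8)
  expect_equal(unname(r$prob["21-30"]), 0.2)
  # steady 2 + casual 21-30: totals 23..32
  r <- resolve_total_category(2, "21-30")
  expect_equal(unname(r$prob["21-30"]), 0.8)
  expect_equal(unname(r$prob["31-40"]), 0.2)
  # exact casual counts sum exactly
  expect_equal(resolve_total_category(0, "7")$total, 7)
  expect_equal(resolve_total_category(5, "0")$total, 5)
  # the selected window stays inside both the category and feasible range
  for (k in 1:20) {
    r <- resolve_total_category(3, "31-40")
    expect_gte(r$window[1], 34)
    expect_lte(r$window[2], 43)
  }
})

test_that("casual splitting rounds half to even and conserves the total", {
  expect_equal(split_casual(10, 0), data.frame(one_off = 0L,
                                               persistent = 10L))
  expect_equal(split_casual(10, 1), data.frame(one_off = 10L,
                                               persistent = 0L))
  # 7 * 0.43 = 3.01 -> 3
  expect_equal(split_casual(7, 0.43)$one_off, 3L)
  # banker's rounding at exact halves: 2.5 -> 2, 3.5 -> 4
  expect_equal(split_casual(5, 0.5)$one_off, 2L)
  expect_equal(split_casual(7, 0.5)$one_off, 4L)
  x <- split_casual(0:30, 0.37)
  expect_true(all(x$one_off + x$persistent == 0:30))
  expect_true(all(x$one_off >= 0 & x$persistent >= 0))
  expect_error(split_casual(5, 1.2))
})

test_that("exact categorical responses are carried over unchanged", {
  sv <- make_cat_survey(steady = c("0", "1", "3", "10+"),
                        casual = c("0", "7", "10", "2"))
  res <- suppressWarnings(assign_integer_counts(sv, seed = 4, max_iter = 5))
  expect_true(all(!res$counts$drawn))
  expect_equal(res$counts$casual, c(0L, 7L, 10L, 2L))
  expect_true(all(res$counts$steady[4] %in% 10:12))
  expect_equal(res$counts$total, res$counts$steady + res$counts$casual)
  # no interval categories: the error is the overall mean/median misfit only
  expect_equal(res$error,
               abs(mean(res$counts$total) - 15.8) +
                 abs(median(res$counts$total) - 5))
})

test_that("within-category draws are close to the enumeration optimum", {
  # 5 respondents in 21-30: exhaustive search over all integer 5-tuples
  grid <- as.matrix(expand.grid(rep(list(21:30), 5)))
  best <- min(abs(rowMeans(grid) - 27.8))
  expect_lte(best, 0.2) # a near-exact tuple exists
  sv <- make_cat_survey(steady = rep("0", 5), casual = rep("21-30", 5))
  # align the overall targets with this single-category population so the
  # error sum scores the within-category draws themselves
  tg <- category_targets(overall = list(mean = 27.8, sd = 2.8, median = 28,
                                        q1 = 25, q3 = 30))
  res <- suppressWarnings(
    assign_integer_counts(sv, targets = tg, seed = 9, max_iter = 60))
  achieved <- abs(mean(res$counts$total) - 27.8)
  expect_lte(achieved, best + 0.75)
})

test_that("reconstruction respects category bounds and conservation", {
  res <- fx_recon("prep_eligibility")
  sv <- fx_survey("prep_eligibility")
  cb <- category_bounds(res$counts$total_category, cap = 312)
  drawn <- res$counts$drawn
  expect_true(all(res$counts$total[drawn] >= cb[drawn, "lo"]))
  expect_true(all(res$counts$total[drawn] <= cb[drawn, "hi"]))
  # casual integers stay inside the reported casual category
  ccb <- category_bounds(sv$casual_count_category, cap = 300)
  expect_true(all(res$counts$casual >= ccb[, "lo"]))
  expect_true(all(res$counts$casual <= ccb[, "hi"]))
  expect_true(all(res$counts$steady <= 12))
  expect_true(all(res$counts$one_off + res$counts$persistent ==
                    res$counts$casual))
})

test_that("best error is non-increasing and runs are reproducible", {
  sv <- make_cat_survey(steady = rep(c("0", "1"), 40),
                        casual = rep(c("11-20", ">50", "3", "21-30"), 20))
  a <- suppressWarnings(assign_integer_counts(sv, seed = 31, max_iter = 40))
  b <- suppressWarnings(assign_integer_counts(sv, seed = 31, max_iter = 40))
  expect_identical(a$counts, b$counts)
  expect_identical(a$error, b$error)
  expect_true(all(diff(a$error_trace) <= 0))
})

test_that("invalid inputs are rejected", {
  expect_error(assign_integer_counts(
    make_cat_survey("0", "eleven"), max_iter = 2), "invalid casual")
  expect_error(assign_integer_counts(
    make_cat_survey("99", "3"), max_iter = 2), "invalid steady")
  bad <- category_targets()
  bad$categories$mean[1] <- 35 # outside 11-20
  expect_error(category_targets(categories = bad$categories), "impossible")
})

test_that("group summaries match hand-computed quantiles", {
  res <- structure(list(counts = data.frame(
    steady = c(0L, 1L, 1L, 0L, 2L, 1L),
    casual = c(2L, 6L, 10L, 0L, 4L, 8L),
    one_off = c(1L, 3L, 5L, 0L, 2L, 4L),
    persistent = c(1L, 3L, 5L, 0L, 2L, 4L))),
    class = "recon_result")
  groups <- c("HA", "HA", "HA", "LA", "LA", "LA")
  ts <- target_summaries(res, groups)
  # HA persistent counts are (1, 3, 5): type-7 quartiles 2, 3, 4
  row <- ts[ts$group == "HA" & ts$type == "casual", ]
  expect_equal(c(row$q1, row$median, row$q3), c(2, 3, 4))
  # LA steady counts are (0, 2, 1) -> sorted (0, 1, 2)
  row <- ts[ts$group == "LA" & ts$type == "steady", ]
  expect_equal(c(row$q1, row$median, row$q3), c(0.5, 1, 1.5))
  # all-zero counts give all-zero summaries
  res$counts[] <- 0L
  ts0 <- target_summaries(res, groups)
  expect_true(all(ts0$median == 0 & ts0$q1 == 0 & ts0$q3 == 0))
  expect_error(target_summaries(res, rep("HA", 6)), "empty group")
})

test_that("HA casual medians dominate LA under the casual-count scenario", {
  sv <- fx_survey("gt15_casual")
  res <- fx_recon("gt15_casual")
  groups <- classify_activity(sv, "gt15_casual", counts = res)
  ts <- target_summaries(res, groups)
  expect_gt(ts$median[ts$group == "HA" & ts$type == "casual"],
            ts$median[ts$group == "LA" & ts$type == "casual"])
})
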