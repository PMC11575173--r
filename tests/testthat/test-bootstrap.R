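test_that("identical groups give a null ratio with its CI containing 1", {
  set.seed(2)
  a <- rnorm(40, 20, 3)
  r <- bootstrap_contrast(a, a, bootstrap_config(seed = 1))
  expect_lte(r$ci_low, 1)
  expect_gte(r$ci_high, 1)
  expect_false(r$significant)
})

test_that("a doubled group is recovered as a significant ratio near 2", {
  set.seed(3)
  a <- rnorm(50, 10, 1)
  r <- bootstrap_contrast(a, 2 * a, bootstrap_config(seed = 4))
  expect_gt(r$point_estimate, 1.9)
  expect_lt(r$point_estimate, 2.1)
  expect_true(r$significant)
})

test_that("difference mode on all-zero groups is exactly degenerate", {
  r <- bootstrap_contrast(numeric(10), numeric(10),
                          bootstrap_config(mode = "difference", seed = 5))
  expect_equal(r$point_estimate, 0)
  expect_equal(r$sd, 0)
  expect_false(r$significant)
})

test_that("the 3-SD band brackets the point estimate symmetrically", {
  set.seed(6)
  r <- bootstrap_contrast(rnorm(30, 10), rnorm(30, 12),
                          bootstrap_config(seed = 7))
  expect_equal(r$band_3sd_high - r$point_estimate, 3 * r$sd)
  expect_equal(r$point_estimate - r$band_3sd_low, 3 * r$sd)
  expect_lte(r$ci_low, r$point_estimate)
  expect_gte(r$ci_high, r$point_estimate)
})

test_that("identical seeds reproduce bootstrap results exactly", {
  set.seed(8); a <- rnorm(30); b <- rnorm(30)
  r1 <- bootstrap_contrast(a, b, bootstrap_config(seed = 9))
  r2 <- bootstrap_contrast(a, b, bootstrap_config(seed = 9))
  expect_identical(r1, r2)
})

test_that("swapping groups inverts the ratio within Monte-Carlo tolerance", {
  set.seed(10)
  a <- rnorm(60, 10, 1); b <- rnorm(60, 15, 1.5)
  r_ab <- bootstrap_contrast(a, b, bootstrap_config(seed = 11))
  r_ba <- bootstrap_contrast(b, a, bootstrap_config(seed = 12))
  expect_equal(r_ab$point_estimate, 1 / r_ba$point_estimate, tolerance = 0.02)
})

test_that("bootstrap SD shrinks with group size", {
  set.seed(13)
  r_small <- bootstrap_contrast(rnorm(10, 10), rnorm(10, 10),
                                bootstrap_config(seed = 14))
  r_large <- bootstrap_contrast(rnorm(100, 10), rnorm(100, 10),
                                bootstrap_config(seed = 15))
  expect_lt(r_large$sd, r_small$sd)
})

test_that("relative-change curves start at the artificial reference point", {
  set.seed(16)
  wd <- list(week2 = list(sham = rnorm(20, 10), lesion = rnorm(20, 5)),
             week3 = list(sham = rnorm(20, 10), lesion = rnorm(20, 10)))
  cur <- relative_change_curve(wd, bootstrap_config(seed = 17))
  expect_equal(cur$window[1], "reference")
  expect_equal(cur$estimate[1], 1)
  expect_equal(cur$estimate[cur$window == "week2"], 0.5, tolerance = 0.1)
  expect_equal(cur$estimate[cur$window == "week3"], 1, tolerance = 0.1)
  # empty window flagged as missing
  wd$week4 <- list(sham = numeric(0), lesion = rnorm(5))
  cur2 <- relative_change_curve(wd, bootstrap_config(seed = 18))
  expect_true(is.na(cur2$estimate[cur2$window == "week4"]))
})

test_that("E-I trajectories pair windows and reject mismatches", {
  set.seed(19)
  mk <- function(shift) {
    lapply(setNames(nm = c("week2", "week3")), function(w) {
      bootstrap_contrast(rnorm(20, 10), rnorm(20, 10 + shift[[w]]),
                         bootstrap_config(mode = "difference", seed = 20))
    })
  }
  e <- mk(list(week2 = 0, week3 = 0))
  i <- mk(list(week2 = 0, week3 = 5))
  tr <- ei_trajectory(e, i, cell_type = "PV_IN")
  expect_equal(nrow(tr), 2)
  expect_equal(tr$delta_e, c(0, 0), tolerance = 0.5)
  expect_equal(tr$delta_i[tr$window == "week3"], 5, tolerance = 0.5)
  expect_error(ei_trajectory(e, i[1], ), "do not match")
})

test_that("degenerate ratio denominators are rejected with a clear error", {
  expect_error(bootstrap_contrast(numeric(10), rnorm(10),
                                  bootstrap_config(seed = 21)),
               "zero denominator")
})
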