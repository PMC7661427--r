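params1 <- adv_params(delta = 1)

test_that("lp_distance sums absolute CDF differences", {
  F1 <- lfd_cdf(lfd(c(`1` = 1, `2` = 1)))   # (0.5, 1)
  G1 <- lfd_cdf(lfd(c(`1` = 1, `2` = 3)))   # (0.25, 1)
  expect_equal(lp_distance(F1, F1), 0)
  expect_equal(lp_distance(F1, G1), 0.25)
  F2 <- lfd_cdf(lfd(c(0L, 4L), classes = 1:2))  # (0, 1)
  G2 <- lfd_cdf(lfd(c(4L, 0L), classes = 1:2))  # (1, 1)
  expect_equal(lp_distance(F2, G2), 1)
  G3 <- lfd_cdf(lfd(c(`5` = 1, `6` = 1)))
  expect_error(lp_distance(F1, G3), "grids")
})

test_that("the three similarity conditions flag the right violations", {
  a <- lfd(c(`1` = 5, `2` = 1, `3` = 5))
  ck <- check_conditions(a, a, params1)
  expect_equal(unname(ck$conditions), c(TRUE, TRUE, TRUE))

  b <- lfd(c(`1` = 5, `2` = 5, `3` = 5))
  ck <- check_conditions(a, b, params1)
  expect_false(ck$conditions[["counts"]])

  o <- lfd(c(`1` = 1, `2` = 5, `3` = 1, `4` = 1, `5` = 5, `6` = 1))
  s <- lfd(c(`1` = 1, `2` = 5, `3` = 1, `4` = 1, `5` = 1, `6` = 5))
  ck <- check_conditions(o, s, adv_params(delta = 1, theta = 0.7, epsilon = 0))
  expect_equal(unname(ck$conditions), c(TRUE, FALSE, TRUE))
})

test_that("the penalized distance reproduces hand-derived values", {
  a <- lfd(c(`1` = 5, `2` = 1, `3` = 5))
  b <- lfd(c(`1` = 5, `2` = 5, `3` = 5))
  d <- dissimilarity(a, b, params1)
  expect_equal(d$l1, 8 / 33, tolerance = 1e-12)
  expect_equal(d$total_D, 10 + 8 / 33, tolerance = 1e-12)
  expect_equal(d$penalty_dim, 10)

  o <- lfd(c(`1` = 1, `2` = 5, `3` = 1, `4` = 1, `5` = 5, `6` = 1))
  s <- lfd(c(`1` = 1, `2` = 5, `3` = 1, `4` = 1, `5` = 1, `6` = 5))
  d <- dissimilarity(o, s, adv_params(delta = 1, theta = 0.7, epsilon = 0))
  expect_equal(d$l1, 2 / 7, tolerance = 1e-12)
  expect_equal(d$penalty_shift, 2)
  expect_equal(d$total_D, 2 + 2 / 7, tolerance = 1e-12)

  x <- lfd(c(`1` = 5, `2` = 1, `3` = 5, `4` = 1, `5` = 5))
  y <- lfd(c(`1` = 3, `2` = 0, `3` = 3, `4` = 0, `5` = 3))
  d <- dissimilarity(x, y, adv_params(delta = 1, theta = 1, epsilon = 0))
  expect_equal(d$penalty_amplitude, 1)      # four pairs x max(0, 1 - 3/4)
  expect_equal(d$total_D, 2 / 17 + 1, tolerance = 1e-12)
})

test_that("self-dissimilarity is exactly zero (property)", {
  set.seed(407)
  for (i in 1:50) {
    x <- random_lfd()
    d <- dissimilarity(x, x, adv_params(delta = sample(c(1, 2, 5), 1)))
    expect_identical(d$total_D, 0)
    expect_true(all(d$condition_flags))
  }
})

test_that("total D is bounded below by the L1 part, equal iff all pass", {
  set.seed(408)
  for (i in 1:60) {
    x <- random_lfd()
    y <- random_lfd()
    # share a grid so both have mass in the evaluation window
    rng <- range(c(x$classes, y$classes))
    p <- adv_params(delta = sample(c(1, 2, 5), 1),
                    theta = runif(1, 0.3, 1), epsilon = sample(0:3, 1),
                    range = rng)
    d <- suppressWarnings(dissimilarity(x, y, p))
    expect_gte(d$total_D, d$l1 - 1e-12)
    if (isTRUE(all(d$condition_flags))) {
      expect_equal(d$total_D, d$l1)
    } else {
      expect_gt(d$total_D, d$l1)
    }
  }
})

test_that("shift penalty shrinks with epsilon, amplitude penalty with theta", {
  set.seed(409)
  for (i in 1:25) {
    x <- random_lfd()
    y <- random_lfd(max_count = 15)
    rng <- range(c(x$classes, y$classes))
    d0 <- suppressWarnings(
      dissimilarity(x, y, adv_params(delta = 2, theta = 0.9, epsilon = 0,
                                     range = rng)))
    d1 <- suppressWarnings(
      dissimilarity(x, y, adv_params(delta = 2, theta = 0.9, epsilon = 2,
                                     range = rng)))
    expect_lte(d1$total_D, d0$total_D + 1e-12)
    d2 <- suppressWarnings(
      dissimilarity(x, y, adv_params(delta = 2, theta = 0.5, epsilon = 0,
                                     range = rng)))
    expect_lte(d2$total_D, d0$total_D + 1e-12)
  }
})

test_that("zero original amplitude differences are skipped with a warning", {
  # Under delta = 2 the fine antimode (class 1) falls into the first
  # smoothed-mode bin, so no robust antimode survives: the merged sequence
  # is two equal-height modes (10, 10) and their amplitude ratio is 0/0.
  o <- lfd(c(10, 2, 3, 4, 10, 1), classes = 0:5)
  cp <- robust_critical_points(o, delta = 2)
  expect_equal(cp$modes, c(0L, 4L))
  expect_equal(cp$antimodes, integer(0))
  expect_warning(check_conditions(o, o, adv_params(delta = 2)), "skipped")
  d <- suppressWarnings(dissimilarity(o, o, adv_params(delta = 2)))
  expect_identical(d$total_D, 0)
})
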