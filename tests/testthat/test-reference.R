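toy <- lfd(c(`1` = 5, `2` = 1, `3` = 5, `4` = 1, `5` = 5))
toy_params <- adv_params(delta = 1, theta = 1, epsilon = 0)

test_that("gamma floors follow the four specifications", {
  x <- lfd(c(`40` = 10, `41` = 3, `42` = 7))
  expect_equal(unname(class_floors(x, gamma_spec("fraction", 0.2))),
               c(2L, 1L, 2L))
  expect_equal(unname(class_floors(x, gamma_spec("adaptive"))),
               c(2L, 3L, 2L))   # sparse class frozen at its count
  expect_equal(unname(class_floors(x, gamma_spec("zero"))), c(0L, 0L, 0L))
  expect_equal(unname(class_floors(x, gamma_spec("absolute", 8))),
               c(8L, 3L, 7L))
})

test_that("the toy sample stops after one accepted thinning iteration", {
  rr <- reference_subsample(toy, toy_params)
  expect_equal(rr$reference$counts, c(4L, 0L, 4L, 0L, 4L))
  expect_equal(rr$iterations_accepted, 1L)
  expect_equal(rr$removed_total, 5L)
  expect_equal(rr$stopping_reason, "amplitude_ratio")
  expect_equal(rr$adv, 2 / 17, tolerance = 1e-12)
  expect_equal(adv(toy, toy_params), rr$adv)
})

test_that("fully frozen classes return the original with ADV zero", {
  p <- adv_params(delta = 1, theta = 1e-6, epsilon = 10,
                  gamma = gamma_spec("fraction", 0.99))
  rr <- reference_subsample(toy, p)
  expect_identical(rr$reference$counts, toy$counts)
  expect_equal(rr$adv, 0)
  expect_equal(rr$stopping_reason, "all_classes_at_floor")
})

test_that("admissibility compares D with the ADV threshold", {
  ia <- is_admissible(toy, toy, toy_params)
  expect_true(ia$admissible)
  expect_equal(ia$D, 0)

  deep <- lfd(c(`1` = 3, `2` = 0, `3` = 3, `4` = 0, `5` = 3))
  ia <- is_admissible(toy, deep, toy_params)
  expect_false(ia$admissible)
  expect_equal(ia$D, 2 / 17 + 1, tolerance = 1e-12)

  ref <- reference_subsample(toy, toy_params)$reference
  ia <- is_admissible(toy, ref, toy_params)
  expect_true(ia$admissible)
  expect_equal(ia$D, ia$adv, tolerance = 1e-12)
})

test_that("a mixture draw thins while preserving the similarity conditions", {
  y <- simulate_mixture(mixture_config(sds = 7, seed = 42))
  p <- adv_params(delta = 5, theta = 0.9, epsilon = 0,
                  gamma = gamma_spec("absolute", 5))
  rr <- reference_subsample(y, p)
  expect_lt(lfd_total(rr$reference), 2000)
  ck <- check_conditions(y, rr$reference, p)
  expect_true(all(ck$conditions))
  d <- dissimilarity(y, rr$reference, p)
  expect_equal(d$total_D, rr$adv, tolerance = 1e-12)
  expect_equal(d$penalty_dim + d$penalty_shift + d$penalty_amplitude, 0)
})

test_that("identical inputs give bit-identical reference results", {
  y <- simulate_mixture(mixture_config(sds = 5, seed = 9))
  p <- adv_params(delta = 5, theta = 0.8, epsilon = 1,
                  gamma = gamma_spec("absolute", 5))
  expect_identical(reference_subsample(y, p), reference_subsample(y, p))
})

test_that("ADV falls with theta and rises with epsilon; size rises with theta", {
  y <- simulate_mixture(mixture_config(sds = 7, seed = 17))
  g <- gamma_spec("absolute", 5)
  thetas <- c(0.4, 0.6, 0.8, 0.95)
  rr <- lapply(thetas, function(th)
    reference_subsample(y, adv_params(delta = 5, theta = th, epsilon = 0,
                                      gamma = g)))
  advs <- vapply(rr, `[[`, numeric(1), "adv")
  sizes <- vapply(rr, function(r) lfd_total(r$reference), numeric(1))
  expect_true(all(diff(advs) <= 1e-12))
  expect_true(all(diff(sizes) >= 0))
  adv_eps <- vapply(c(0, 1, 3), function(e)
    adv(y, adv_params(delta = 5, theta = 0.9, epsilon = e, gamma = g)),
    numeric(1))
  expect_true(all(diff(adv_eps) >= -1e-12))
})

test_that("the rejected candidate one step past the reference violates a condition", {
  set.seed(410)
  for (i in 1:20) {
    x <- random_lfd(max_classes = 15, max_count = 15)
    p <- adv_params(delta = sample(c(1, 2), 1), theta = runif(1, 0.5, 1),
                    epsilon = sample(0:1, 1))
    rr <- suppressWarnings(reference_subsample(x, p))
    ck <- suppressWarnings(check_conditions(x, rr$reference, p))
    expect_true(all(ck$conditions))
    if (rr$stopping_reason != "all_classes_at_floor") {
      fl <- class_floors(x, p$gamma)
      cand <- pmax(rr$reference$counts - 1L, unname(fl))
      if (sum(cand) > 0) {
        ck2 <- suppressWarnings(
          check_conditions(x, lfd(cand, classes = x$classes), p))
        expect_false(isTRUE(all(ck2$conditions)))
      }
    }
  }
})
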