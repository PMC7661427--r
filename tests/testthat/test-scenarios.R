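# In-code record fixtures for scenario tests.
make_records <- function(trip, haul, lengths, catch = 1000, factor = 1,
                         when = "2018-07-15 12:00:00") {
  data.frame(trip_id = trip, haul_id = haul,
             haul_datetime = as.POSIXct(when, tz = "UTC"),
             haul_catch_kg = catch, length_cm = as.integer(lengths),
             n_measured = 1L, raising_factor = factor,
             stringsAsFactors = FALSE)
}

test_that("aggregation raises, sums and rounds once per class", {
  r <- make_records("T1", "H1", 50, factor = 3)
  r$n_measured <- 2L
  expect_equal(aggregate_lfd(r)$counts, 6L)
  expect_equal(aggregate_lfd(r)$classes, 50L)

  r2 <- make_records("T1", "H1", c(40, 40, 41))
  expect_equal(aggregate_lfd(r2)$counts, c(2L, 1L))

  r3 <- rbind(make_records("T1", "H1", 50, factor = 1.3),
              make_records("T1", "H2", 50, factor = 1.3))
  expect_equal(aggregate_lfd(r3)$counts, 3L)  # 2.6 rounds half away from zero
})

test_that("aggregation is additive over disjoint subsets up to rounding", {
  rec <- synthetic_hierarchical_data(seed = 21)
  split_at <- rec$trip_id == "T01"
  a <- aggregate_lfd(rec[split_at, ])
  b <- aggregate_lfd(rec[!split_at, ])
  whole <- aggregate_lfd(rec)
  grid <- whole$classes
  av <- integer(length(grid)); av[match(a$classes, grid)] <- a$counts
  bv <- integer(length(grid)); bv[match(b$classes, grid)] <- b$counts
  expect_true(all(abs(av + bv - whole$counts) <= 1))
})

test_that("the empty scenario is the identity with D exactly zero", {
  rec <- synthetic_hierarchical_data(seed = 22)
  p <- adv_params(delta = 5, theta = 0.7, epsilon = 3,
                  gamma = gamma_spec("adaptive"), range = c(40, 80))
  sc <- apply_scenario(rec, p)
  expect_identical(sc$D, 0)
  expect_true(sc$admissible)
})

test_that("out-of-range mass is ignored when dropping a trip", {
  # trip X alone carries every fish above 90 cm; with the important range at
  # [40, 80] its removal leaves D = 0
  base <- make_records("A", "H1", rep(c(50, 60, 70), times = c(30, 10, 30)))
  big <- make_records("X", "H2", rep(c(95, 100, 110), each = 15))
  rec <- rbind(base, big)
  p <- adv_params(delta = 5, theta = 0.9, epsilon = 0, range = c(40, 80))
  sc <- apply_scenario(rec, p, drop_trips = "X")
  expect_equal(sc$D, 0)
  expect_true(sc$admissible)
})

test_that("dropping the trip holding the upper mode breaks condition (1)", {
  lower <- make_records("A", "H1", rep(c(41, 45, 49, 55, 61, 65, 69),
                                       times = c(20, 40, 20, 5, 20, 40, 20)))
  upper <- make_records("B", "H2", rep(c(95, 100, 105),
                                       times = c(20, 45, 20)))
  rec <- rbind(lower, upper)
  p <- adv_params(delta = 5, theta = 0.5, epsilon = 5)
  orig <- aggregate_lfd(rec)
  expect_length(robust_critical_points(orig, 5)$modes, 3)
  sc <- apply_scenario(rec, p, drop_trips = "B")
  expect_gte(sc$D, p$c1)
  expect_false(sc$admissible)
})

test_that("haul filters drop light hauls and night hauls", {
  day <- make_records("A", "H1", rep(50, 20), catch = 5000,
                      when = "2018-07-15 12:00:00")
  night <- make_records("A", "H2", rep(60, 20), catch = 5000,
                        when = "2018-07-15 23:30:00")
  light <- make_records("A", "H3", rep(70, 20), catch = 900,
                        when = "2018-07-15 08:00:00")
  rec <- rbind(day, night, light)
  p <- adv_params(delta = 5, theta = 0.5, epsilon = 5)
  sc <- apply_scenario(rec, p, min_haul_catch_kg = 3000,
                       drop_time_window = c(21, 3))
  # only the day haul remains: 20 fish at 50 cm
  expect_equal(sc$sizes$size_unraised, 20)
  expect_equal(sc$mean_length, 50)
})

test_that("individual thinning medians are stable across seed batches", {
  rec <- synthetic_hierarchical_data(seed = 23)
  p <- adv_params(delta = 5, theta = 0.7, epsilon = 3,
                  gamma = gamma_spec("adaptive"), range = c(40, 80))
  base_lfd <- aggregate_lfd(rec)
  baseline <- list(lfd = base_lfd, adv = adv(base_lfd, p))
  s1 <- apply_scenario(rec, p, keep_fraction_per_haul = 0.5,
                       replicates = 150, seed = 101, baseline = baseline)
  s2 <- apply_scenario(rec, p, keep_fraction_per_haul = 0.5,
                       replicates = 150, seed = 202, baseline = baseline)
  iqr <- stats::IQR(s1$D_replicates)
  expect_lt(abs(s1$D - s2$D), iqr)
  expect_equal(s1$replicates, 150)
})

test_that("variance components handle degenerate designs", {
  r <- make_records("A", "H1", rep(55, 10))
  vc <- mean_length_varcomp(r)
  expect_equal(vc$mu, 55)
  expect_equal(vc$var_trip + vc$var_haul + vc$var_within, 0)
  expect_equal(vc$se_mean, 0)

  r2 <- make_records("A", "H1", c(50, 52, 58, 60))
  vc2 <- mean_length_varcomp(r2)
  expect_equal(vc2$var_trip, 0)
  expect_equal(vc2$var_haul, 0)
  expect_equal(vc2$var_within, stats::var(c(50, 52, 58, 60)))
})

test_that("moment estimates match REML on balanced data with clear components", {
  skip_if_not_installed("lme4")
  rec <- synthetic_hierarchical_data(
    n_trips = 12, hauls_per_trip = 6, fish_per_haul = 25,
    mixture = mixture_config(weights = 1, means = 60, sds = 4, n = 1),
    trip_sd = 3, haul_sd = 2, seed = 31)
  vc <- mean_length_varcomp(rec)
  y <- rep(rec$length_cm, rec$n_measured)
  df <- data.frame(y = y, trip = rep(rec$trip_id, rec$n_measured),
                   haul = rep(paste(rec$trip_id, rec$haul_id), rec$n_measured))
  fit <- lme4::lmer(y ~ 1 + (1 | trip) + (1 | haul), data = df, REML = TRUE)
  vv <- as.data.frame(lme4::VarCorr(fit))
  reml <- c(trip = vv$vcov[vv$grp == "trip"],
            haul = vv$vcov[vv$grp == "haul"],
            within = vv$vcov[vv$grp == "Residual"])
  # balanced design: ANOVA moments and REML coincide when interior
  expect_equal(vc$var_trip, unname(reml["trip"]), tolerance = 0.02)
  expect_equal(vc$var_haul, unname(reml["haul"]), tolerance = 0.02)
  expect_equal(vc$var_within, unname(reml["within"]), tolerance = 0.02)
})
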