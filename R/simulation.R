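# Monte Carlo machinery: normal-mixture length generators, the (theta,
# epsilon, sd) grid study of reference-subsample size and ADV, the
# bootstrap-subsampling comparison with CDF band coverage, the two-dataset
# contrast, and a synthetic hierarchical trip/haul/fish generator.

#' Normal-mixture configuration for simulated length samples
#'
#' The canonical three-cohort configuration is a superposition
#' `1/4 N(40, sd) + 1/2 N(70, sd) + 1/4 N(100, sd)` of 2000 fish, emulating
#' three age clusters in a length sample.
#'
#' @param weights Mixture weights (nonnegative, summing to 1).
#' @param means Component means in cm.
#' @param sds Component standard deviations in cm (scalar recycled).
#' @param n Sample size.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `mixture_config`.
#' @export
mixture_config <- function(weights = c(0.25, 0.5, 0.25),
                           means = c(40, 70, 100),
                           sds = 5, n = 2000, seed = 1) {
  if (length(sds) == 1L) sds <- rep(sds, length(means))
  if (length(weights) != length(means) || length(sds) != length(means))
    stop("weights, means and sds must have equal length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  if (any(sds <= 0)) stop("sds must be positive")
  if (n < 1) stop("n must be >= 1")
  structure(list(weights = weights, means = means, sds = sds,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "mixture_config")
}

# Draw n rounded mixture lengths using the current RNG state; values below
# 1 cm are redrawn (component and deviate).
.mixture_lengths <- function(n, weights, means, sds) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  y <- round_half_up(stats::rnorm(n, means[comp], sds[comp]))
  bad <- which(y < 1)
  while (length(bad)) {
    comp <- sample.int(length(weights), length(bad), replace = TRUE,
                       prob = weights)
    y[bad] <- round_half_up(stats::rnorm(length(bad), means[comp], sds[comp]))
    bad <- bad[y[bad] < 1]
  }
  as.integer(y)
}

#' Simulate a length sample from a normal mixture
#'
#' Component membership is drawn by the mixture weights, the normal deviate
#' is rounded to the nearest cm, and draws below 1 cm are redrawn. The draw
#' is deterministic given `config$seed`.
#'
#' @param config A [mixture_config()].
#' @param as Return an `lfd` (default) or the raw integer `lengths`.
#' @return An `lfd` or an integer vector of lengths.
#' @export
simulate_mixture <- function(config, as = c("lfd", "lengths")) {
  stopifnot(inherits(config, "mixture_config"))
  as <- match.arg(as)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  y <- .mixture_lengths(config$n, config$weights, config$means, config$sds)
  if (as == "lengths") y else build_lfd(y, label = "simulated mixture")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Per-replicate reference-path evaluation over a (theta, epsilon) grid.
# Returns size and adv matrices (cells in row-major order of expand.grid)
# plus what bootstrap_comparison needs (lengths, pre, floors, accepted idx).
.replicate_grid <- function(lengths, cells, params_base) {
  x <- build_lfd(lengths)
  pre <- .orig_pre(x, params_base)
  floors <- unname(class_floors(x, params_base$gamma, params_base$range))
  path <- .reference_path(pre, floors,
                          theta_min = min(cells$theta),
                          eps_max = max(cells$epsilon))
  acc <- integer(nrow(cells))
  advs <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    stp <- .stop_from_path(path, cells$theta[k], cells$epsilon[k])
    acc[k] <- stp$accepted
    advs[k] <- if (stp$accepted == 0L) 0 else path$l1[stp$accepted]
  }
  size <- vapply(acc, function(i) sum(pmax(pre$counts - i, floors)),
                 numeric(1))
  list(pre = pre, floors = floors, accepted = acc, size = size, adv = advs)
}

#' Grid study of reference-subsample size and ADV
#'
#' For each mixture spread `sd` and each `(theta, epsilon)` cell, simulates
#' `replicates` length samples, builds the reference subsample of each, and
#' averages the reference size and ADV per cell. Within a replicate, one
#' sample draw serves all cells (the deterministic thinning path is shared;
#' `theta` and `epsilon` only select the stopping step), so the monotone
#' trends in `theta` and `epsilon` hold exactly per replicate.
#'
#' @param sds Mixture component standard deviations to study (cm).
#' @param thetas,epsilons Parameter grids.
#' @param n Sample size per replicate.
#' @param gamma A [gamma_spec()] (default: at least 5 fish per class).
#' @param delta Smoothing bandwidth (cm).
#' @param replicates Monte Carlo replicates per `sd`.
#' @param seed Integer seed.
#' @param weights,means Mixture weights and means (the three-cohort default).
#' @return A data.frame (class `grid_result`) with columns `sd`, `theta`,
#'   `epsilon`, `mean_size`, `mean_adv`, `replicates`.
#' @export
grid_study <- function(sds = c(5, 7, 10),
                       thetas = seq(0.30, 0.95, by = 0.05),
                       epsilons = 0:3,
                       n = 2000,
                       gamma = gamma_spec("absolute", 5),
                       delta = 5,
                       replicates = 100,
                       seed = 1,
                       weights = c(0.25, 0.5, 0.25),
                       means = c(40, 70, 100)) {
  cells <- expand.grid(theta = thetas, epsilon = epsilons,
                       KEEP.OUT.ATTRS = FALSE)
  params_base <- adv_params(delta = delta, gamma = gamma)
  old <- .save_rng(); on.exit(.restore_rng(old))
  out <- vector("list", length(sds))
  for (si in seq_along(sds)) {
    set.seed(seed + si - 1L)
    size_sum <- numeric(nrow(cells))
    adv_sum <- numeric(nrow(cells))
    for (r in seq_len(replicates)) {
      y <- .mixture_lengths(n, weights, means, rep(sds[si], length(means)))
      rg <- .replicate_grid(y, cells, params_base)
      size_sum <- size_sum + rg$size
      adv_sum <- adv_sum + rg$adv
    }
    out[[si]] <- data.frame(sd = sds[si], theta = cells$theta,
                            epsilon = cells$epsilon,
                            mean_size = size_sum / replicates,
                            mean_adv = adv_sum / replicates,
                            replicates = replicates)
  }
  res <- do.call(rbind, out)
  class(res) <- c("grid_result", "data.frame")
  res
}

#' @export
plot.grid_result <- function(x, what = c("mean_size", "mean_adv"), ...) {
  what <- match.arg(what)
  sds <- unique(x$sd)
  oldpar <- graphics::par(mfrow = c(1, length(sds)))
  on.exit(graphics::par(oldpar))
  for (s in sds) {
    xs <- x[x$sd == s, ]
    wide <- stats::reshape(xs[, c("theta", "epsilon", what)],
                           idvar = "theta", timevar = "epsilon",
                           direction = "wide")
    graphics::matplot(wide$theta, wide[, -1], type = "b", pch = 1,
                      xlab = expression(theta), ylab = what,
                      main = sprintf("sd = %g", s), ...)
  }
  invisible(x)
}

# D for a subsample count vector on the original's grid, given precomputed
# original statistics; used in the bootstrap inner loop.
.dissim_counts <- function(pre, xs, F0, theta, epsilon, c1, c2, c3) {
  st <- .cond_stats(pre, xs)
  l1 <- sum(abs(F0 - cumsum(xs) / sum(xs)))
  if (!st$dim_ok) return(l1 + c1)
  l1 + c2 * sum(pmax(0, st$merged_shift - epsilon)) +
    c3 * sum(pmax(0, theta - st$ratios))
}

#' Bootstrap-subsampling comparison and CDF band coverage
#'
#' For each Monte Carlo replicate of the original mixture sample and each
#' `(theta, epsilon)` cell: the reference subsample and its size are
#' computed; bootstrap subsamples of the cell's mean reference size are
#' drawn (without replacement by default) from the original draw; the
#' penalized dissimilarity `D` of each bootstrap subsample to the original
#' is averaged per replicate, then grand-averaged over replicates and cells.
#' Coverage is the fraction of replicates whose reference-subsample CDF lies
#' entirely within the pointwise 2.5-97.5 percentile band of the bootstrap
#' CDFs.
#'
#' @param config A [mixture_config()] for the original sample (its `seed` is
#'   ignored; use `seed`).
#' @param thetas,epsilons Parameter grids.
#' @param replicates Monte Carlo replicates.
#' @param n_boot Bootstrap subsamples per replicate and cell.
#' @param seed Integer seed.
#' @param gamma,delta As in [grid_study()].
#' @param replace Draw bootstrap subsamples with replacement (default
#'   `FALSE`: subsampling without replacement).
#' @param c1,c2,c3 Penalty constants for `D`.
#' @return A list (class `bootstrap_comparison`): `grand_mean_D`, `by_cell`
#'   (data.frame with `theta`, `epsilon`, `mean_size`, `boot_size`,
#'   `mean_adv`, `mean_D`, `coverage`), `replicates`, `n_boot`.
#' @export
bootstrap_comparison <- function(config = mixture_config(sds = 7),
                                 thetas = seq(0.30, 0.95, by = 0.05),
                                 epsilons = 0:3,
                                 replicates = 100,
                                 n_boot = 100,
                                 seed = 1,
                                 gamma = gamma_spec("absolute", 5),
                                 delta = 5,
                                 replace = FALSE,
                                 c1 = 10, c2 = 2, c3 = 1) {
  stopifnot(inherits(config, "mixture_config"))
  cells <- expand.grid(theta = thetas, epsilon = epsilons,
                       KEEP.OUT.ATTRS = FALSE)
  nc <- nrow(cells)
  params_base <- adv_params(delta = delta, gamma = gamma)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  reps <- vector("list", replicates)
  size_mat <- matrix(0, replicates, nc)
  adv_mat <- matrix(0, replicates, nc)
  for (r in seq_len(replicates)) {
    y <- .mixture_lengths(config$n, config$weights, config$means, config$sds)
    rg <- .replicate_grid(y, cells, params_base)
    reps[[r]] <- list(lengths = y, pre = rg$pre, floors = rg$floors,
                      accepted = rg$accepted)
    size_mat[r, ] <- rg$size
    adv_mat[r, ] <- rg$adv
  }
  boot_size <- pmax(1L, as.integer(round(colMeans(size_mat))))
  mean_D <- matrix(NA_real_, replicates, nc)
  covered <- matrix(NA, replicates, nc)
  for (r in seq_len(replicates)) {
    rep_r <- reps[[r]]
    pre <- rep_r$pre
    K <- length(pre$grid)
    n <- length(rep_r$lengths)
    pop <- rep_r$lengths - pre$grid[1L] + 1L
    F0 <- cumsum(pre$counts) / sum(pre$counts)
    for (k in seq_len(nc)) {
      m <- boot_size[k]
      Ds <- numeric(n_boot)
      cdfs <- matrix(0, n_boot, K)
      for (b in seq_len(n_boot)) {
        idx <- if (replace) sample.int(n, m, replace = TRUE)
               else sample.int(n, m)
        xs <- tabulate(pop[idx], nbins = K)
        Ds[b] <- .dissim_counts(pre, xs, F0, cells$theta[k],
                                cells$epsilon[k], c1, c2, c3)
        cdfs[b, ] <- cumsum(xs) / m
      }
      mean_D[r, k] <- mean(Ds)
      ref_counts <- pmax(pre$counts - rep_r$accepted[k], rep_r$floors)
      Gref <- cumsum(ref_counts) / sum(ref_counts)
      band <- apply(cdfs, 2, stats::quantile, probs = c(0.025, 0.975),
                    names = FALSE)
      covered[r, k] <- all(Gref >= band[1L, ] & Gref <= band[2L, ])
    }
  }
  by_cell <- data.frame(theta = cells$theta, epsilon = cells$epsilon,
                        mean_size = colMeans(size_mat),
                        boot_size = boot_size,
                        mean_adv = colMeans(adv_mat),
                        mean_D = colMeans(mean_D),
                        coverage = colMeans(covered))
  structure(list(grand_mean_D = mean(mean_D), by_cell = by_cell,
                 replicates = replicates, n_boot = n_boot,
                 config = config),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf(
    "Bootstrap subsampling comparison (%d replicates x %d draws per cell)\n",
    x$replicates, x$n_boot))
  cat(sprintf("  grand mean D(original, bootstrap subsample): %.4f\n",
              x$grand_mean_D))
  cat(sprintf("  mean ADV over cells: %.4f\n", mean(x$by_cell$mean_adv)))
  invisible(x)
}

#' Contrast two simulated datasets through the ADV
#'
#' Computes, for every `(theta, epsilon)` cell, the ADV of dataset 1 and the
#' penalized dissimilarity `D` between dataset 1 and dataset 2; a dataset
#' that is genuinely different should give `D > ADV` everywhere, whereas a
#' second draw from the same configuration should not.
#'
#' @param config1,config2 [mixture_config()]s (their `seed`s are used).
#' @param thetas,epsilons Parameter grids.
#' @param gamma,delta As in [grid_study()].
#' @param c1,c2,c3 Penalty constants.
#' @return A data.frame with columns `theta`, `epsilon`, `adv`, `D`,
#'   `exceeds` (`D > adv`).
#' @export
contrast_datasets <- function(config1,
                              config2,
                              thetas = seq(0.30, 0.95, by = 0.05),
                              epsilons = c(0, 3),
                              gamma = gamma_spec("absolute", 5),
                              delta = 5,
                              c1 = 10, c2 = 2, c3 = 1) {
  d1 <- simulate_mixture(config1)
  d2 <- simulate_mixture(config2)
  cells <- expand.grid(theta = thetas, epsilon = epsilons,
                       KEEP.OUT.ATTRS = FALSE)
  params_base <- adv_params(delta = delta, gamma = gamma)
  rg <- .replicate_grid(simulate_mixture(config1, as = "lengths"), cells,
                        params_base)
  # D(d1, d2) on the union grid; condition statistics are cell-independent
  pre <- .orig_pre(d1, params_base)
  al <- .sub_on_grid(pre, d2, NULL)
  pre2 <- pre; pre2$grid <- al$grid; pre2$counts <- al$orig
  st <- .cond_stats(pre2, al$sub)
  l1 <- .l1_counts(al$orig, al$sub)
  D <- vapply(seq_len(nrow(cells)), function(k) {
    if (!st$dim_ok) return(l1 + c1)
    l1 + c2 * sum(pmax(0, st$merged_shift - cells$epsilon[k])) +
      c3 * sum(pmax(0, cells$theta[k] - st$ratios))
  }, numeric(1))
  data.frame(theta = cells$theta, epsilon = cells$epsilon,
             adv = rg$adv, D = D, exceeds = D > rg$adv)
}

#' Generate synthetic hierarchical trip/haul/fish records
#'
#' A stylized emulation of observer length sampling: fish lengths follow a
#' normal mixture with additive trip- and haul-level mean shifts
#' (intra-haul correlation), rounded to 1 cm and clamped at 1 cm; each haul
#' gets a uniform time of day, a uniform total catch weight, and a raising
#' factor equal to catch weight over the measured-sample weight implied by a
#' cubic length-weight relation (at least 1). One record per measured fish.
#'
#' @param n_trips,hauls_per_trip,fish_per_haul Design sizes.
#' @param mixture A [mixture_config()] for the marginal length distribution
#'   (its `n` and `seed` are ignored).
#' @param trip_sd,haul_sd Standard deviations (cm) of the trip and haul mean
#'   shifts.
#' @param catch_kg_range Range of haul total catch weights (kg).
#' @param seed Integer seed.
#' @return A data.frame of measurement records with columns `trip_id`,
#'   `haul_id`, `haul_datetime`, `haul_catch_kg`, `length_cm`, `n_measured`,
#'   `raising_factor`.
#' @export
synthetic_hierarchical_data <- function(n_trips = 3,
                                        hauls_per_trip = 8,
                                        fish_per_haul = 27,
                                        mixture = mixture_config(sds = 7),
                                        trip_sd = 2,
                                        haul_sd = 3,
                                        catch_kg_range = c(500, 6000),
                                        seed = 1) {
  stopifnot(n_trips >= 1, hauls_per_trip >= 1, fish_per_haul >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n_hauls <- n_trips * hauls_per_trip
  n_fish <- n_hauls * fish_per_haul
  trip_eff <- stats::rnorm(n_trips, 0, trip_sd)
  haul_eff <- stats::rnorm(n_hauls, 0, haul_sd)
  haul_trip <- rep(seq_len(n_trips), each = hauls_per_trip)
  base <- .mixture_lengths(n_fish, mixture$weights, mixture$means,
                           mixture$sds)
  fish_haul <- rep(seq_len(n_hauls), each = fish_per_haul)
  len <- round_half_up(base + trip_eff[haul_trip[fish_haul]] +
                         haul_eff[fish_haul])
  len <- pmax(1L, as.integer(len))
  day <- as.POSIXct("2018-07-15 00:00:00", tz = "UTC")
  haul_time <- day + round(stats::runif(n_hauls, 0, 86399))
  haul_catch <- stats::runif(n_hauls, catch_kg_range[1], catch_kg_range[2])
  # cubic length-weight relation, a = 0.01 g/cm^3
  w_kg <- 0.01 * len^3 / 1000
  measured_kg <- as.vector(rowsum(w_kg, fish_haul))
  raising <- pmax(1, haul_catch / measured_kg)
  data.frame(
    trip_id = sprintf("T%02d", haul_trip[fish_haul]),
    haul_id = sprintf("T%02d-H%02d", haul_trip[fish_haul],
                      rep(rep(seq_len(hauls_per_trip), each = fish_per_haul),
                          n_trips)),
    haul_datetime = haul_time[fish_haul],
    haul_catch_kg = haul_catch[fish_haul],
    length_cm = len,
    n_measured = 1L,
    raising_factor = raising[fish_haul],
    stringsAsFactors = FALSE
  )
}
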