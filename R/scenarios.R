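# Sampling-effort reduction scenarios on hierarchical trip/haul/fish
# records: raised LFD aggregation, trip/haul/individual elimination with
# admissibility against the baseline ADV, and nested random-effects
# mean-length summaries.

.record_cols <- c("trip_id", "haul_id", "haul_datetime", "haul_catch_kg",
                  "length_cm", "n_measured", "raising_factor")

.validate_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  miss <- setdiff(.record_cols, names(records))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  chk <- function(col, bad, what) {
    i <- which(bad)
    if (length(i))
      stop(sprintf("invalid %s in column '%s' at row %d", what, col, i[1L]))
  }
  chk("length_cm", !is.finite(records$length_cm) | records$length_cm < 1 |
        records$length_cm != round(records$length_cm), "length (positive integer cm)")
  chk("n_measured", !is.finite(records$n_measured) | records$n_measured < 1 |
        records$n_measured != round(records$n_measured), "count")
  chk("raising_factor", !is.finite(records$raising_factor) |
        records$raising_factor < 1, "raising factor (must be >= 1)")
  chk("haul_catch_kg", !is.finite(records$haul_catch_kg) |
        records$haul_catch_kg < 0, "catch weight")
  chk("haul_datetime", is.na(records$haul_datetime), "timestamp")
  invisible(records)
}

#' Aggregate measurement records into a raised length-frequency distribution
#'
#' Per length class, the raised count is the sum of `n_measured *
#' raising_factor` over records, rounded to the nearest integer (ties away
#' from zero) once after aggregation.
#'
#' @param records Measurement records (see [read_records()] for the dialect).
#' @param range Optional important range to restrict to.
#' @return An `lfd` of raised counts.
#' @export
aggregate_lfd <- function(records, range = NULL) {
  .validate_records(records)
  if (!nrow(records)) stop("no records")
  raised <- rowsum(records$n_measured * records$raising_factor,
                   records$length_cm)
  cls <- as.integer(rownames(raised))
  counts <- as.integer(round_half_up(as.vector(raised)))
  keep <- counts > 0
  out <- lfd(counts[keep], cls[keep], label = "raised LFD")
  restrict(out, range)
}

.filter_records <- function(records, drop_trips = NULL,
                            min_haul_catch_kg = NULL,
                            drop_time_window = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(drop_trips))
    keep <- keep & !(records$trip_id %in% drop_trips)
  if (!is.null(min_haul_catch_kg))
    keep <- keep & records$haul_catch_kg >= min_haul_catch_kg
  if (!is.null(drop_time_window)) {
    lt <- as.POSIXlt(records$haul_datetime)
    hour <- lt$hour + lt$min / 60 + lt$sec / 3600
    a <- drop_time_window[1L]; b <- drop_time_window[2L]
    inside <- if (a <= b) hour >= a & hour < b else hour >= a | hour < b
    keep <- keep & !inside
  }
  records[keep, , drop = FALSE]
}

# Thin measured individuals per haul without replacement, keeping the stated
# fraction (rounded count per haul); raising factors are reapplied as-is.
.thin_individuals <- function(records, keep_fraction) {
  idx <- rep(seq_len(nrow(records)), records$n_measured)
  haul <- records$haul_id[idx]
  kept <- unlist(lapply(split(seq_along(idx), haul), function(ii) {
    k <- round_half_up(keep_fraction * length(ii))
    if (k <= 0) return(integer(0))
    sample(ii, k)
  }), use.names = FALSE)
  if (!length(kept)) stop("scenario removed all records")
  tab <- table(idx[kept])
  out <- records[as.integer(names(tab)), , drop = FALSE]
  out$n_measured <- as.integer(tab)
  out
}

#' Evaluate a sampling-effort reduction scenario
#'
#' Filters the record set (dropping whole trips, light hauls, and/or hauls
#' in a daily time window), optionally thins measured individuals per haul,
#' re-aggregates the raised LFD, and scores it against the full baseline:
#' penalized dissimilarity `D`, admissibility `D <= ADV`, raised/unraised
#' sample sizes, and the mean length with its nested random-effects standard
#' error. Individual thinning is replicated and the median `D` reported.
#'
#' @param records Full measurement records (the baseline).
#' @param params An [adv_params()].
#' @param drop_trips Character vector of trip ids to eliminate.
#' @param min_haul_catch_kg Drop hauls with total catch below this weight.
#' @param drop_time_window Numeric `c(start_hour, end_hour)` daily interval
#'   of haul times to drop; wraps midnight when `start > end` (e.g.
#'   `c(21, 3)` drops night hauls between 21:00 and 03:00).
#' @param keep_fraction_per_haul Fraction of measured individuals retained
#'   per haul (drawn without replacement), or `NULL`.
#' @param replicates Replicates for the individual-thinning draw.
#' @param seed Integer seed for the thinning draws.
#' @param baseline Optional precomputed list with elements `lfd` and `adv`
#'   for the full records (recomputed when `NULL`).
#' @return An object of class `scenario_result`.
#' @export
apply_scenario <- function(records, params = adv_params(),
                           drop_trips = NULL,
                           min_haul_catch_kg = NULL,
                           drop_time_window = NULL,
                           keep_fraction_per_haul = NULL,
                           replicates = 100,
                           seed = 1,
                           baseline = NULL) {
  .validate_records(records)
  if (is.null(baseline)) {
    base_lfd <- aggregate_lfd(records)
    baseline <- list(lfd = base_lfd, adv = adv(base_lfd, params))
  }
  filt <- .filter_records(records, drop_trips, min_haul_catch_kg,
                          drop_time_window)
  if (!nrow(filt)) stop("scenario removed all records")
  desc <- c(
    if (!is.null(drop_trips))
      sprintf("drop trips: %s", paste(drop_trips, collapse = ", ")),
    if (!is.null(min_haul_catch_kg))
      sprintf("drop hauls < %g kg catch", min_haul_catch_kg),
    if (!is.null(drop_time_window))
      sprintf("drop hauls in [%02.0f:00, %02.0f:00)", drop_time_window[1L],
              drop_time_window[2L]),
    if (!is.null(keep_fraction_per_haul))
      sprintf("keep %.0f%% of individuals per haul",
              100 * keep_fraction_per_haul)
  )
  if (is.null(desc)) desc <- "no filters (baseline)"
  score_one <- function(recs) {
    sub <- aggregate_lfd(recs)
    D <- dissimilarity(baseline$lfd, sub, params)$total_D
    vc <- suppressWarnings(mean_length_varcomp(recs, params$range))
    sub_r <- restrict(sub, params$range)
    unraised <- rep(recs$length_cm, recs$n_measured)
    in_range <- if (is.null(params$range)) rep(TRUE, length(unraised))
    else unraised >= params$range$low & unraised <= params$range$high
    list(D = D,
         size_raised = sum(sub$counts), size_raised_range = sum(sub_r$counts),
         size_unraised = length(unraised),
         size_unraised_range = sum(in_range),
         mean_length = vc$mu, se_mean_length = vc$se_mean)
  }
  if (is.null(keep_fraction_per_haul)) {
    sc <- score_one(filt)
    res <- list(description = paste(desc, collapse = "; "),
                D = sc$D, admissible = sc$D <= baseline$adv,
                adv = baseline$adv,
                sizes = sc[c("size_raised", "size_raised_range",
                             "size_unraised", "size_unraised_range")],
                mean_length = sc$mean_length,
                se_mean_length = sc$se_mean_length,
                replicates = 1L, D_replicates = sc$D)
  } else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    runs <- lapply(seq_len(replicates), function(i)
      score_one(.thin_individuals(filt, keep_fraction_per_haul)))
    Ds <- vapply(runs, `[[`, numeric(1), "D")
    med <- stats::median(Ds)
    sizes <- lapply(c("size_raised", "size_raised_range", "size_unraised",
                      "size_unraised_range"), function(f)
                        mean(vapply(runs, `[[`, numeric(1), f)))
    names(sizes) <- c("size_raised", "size_raised_range", "size_unraised",
                      "size_unraised_range")
    res <- list(description = paste(desc, collapse = "; "),
                D = med, admissible = med <= baseline$adv,
                adv = baseline$adv, sizes = sizes,
                mean_length = mean(vapply(runs, `[[`, numeric(1),
                                          "mean_length")),
                se_mean_length = mean(vapply(runs, `[[`, numeric(1),
                                             "se_mean_length")),
                replicates = replicates, D_replicates = Ds)
  }
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Sampling-effort scenario:", x$description, "\n")
  what <- if (x$replicates > 1) sprintf("median over %d replicates", x$replicates)
  else "deterministic"
  cat(sprintf("  D = %.4f (%s), ADV = %.4f -> %s\n", x$D, what, x$adv,
              if (x$admissible) "admissible" else "NOT admissible"))
  cat(sprintf("  raised size %0.f (in range %0.f); unraised %0.f (in range %0.f)\n",
              x$sizes$size_raised, x$sizes$size_raised_range,
              x$sizes$size_unraised, x$sizes$size_unraised_range))
  cat(sprintf("  mean length %.2f cm (se %.2f)\n", x$mean_length,
              x$se_mean_length))
  invisible(x)
}

#' Nested random-effects mean length and variance components
#'
#' Fits the nested model `length = mu + trip + haul + residual` by
#' method-of-moments nested ANOVA (unbalanced two-fold design) on unraised
#' measured lengths within the important range. Negative moment estimates
#' are truncated to zero with a warning. The standard error of the grand
#' mean combines the three components with the design counts.
#'
#' @param records Measurement records.
#' @param range Optional important range restricting the lengths used.
#' @return An object of class `varcomp`: `mu`, `var_trip`, `var_haul`,
#'   `var_within` (cm^2), `se_mean` (cm), and design counts.
#' @export
mean_length_varcomp <- function(records, range = NULL) {
  .validate_records(records)
  range <- .as_range(range)
  keep <- if (is.null(range)) rep(TRUE, nrow(records))
  else records$length_cm >= range$low & records$length_cm <= range$high
  recs <- records[keep, , drop = FALSE]
  if (!nrow(recs)) stop("no records in important range")
  y <- rep(recs$length_cm, recs$n_measured)
  trip <- rep(recs$trip_id, recs$n_measured)
  haul <- rep(paste(recs$trip_id, recs$haul_id, sep = "\r"), recs$n_measured)
  N <- length(y)
  mu <- mean(y)
  if (N == 1L) {
    warning("single observation: variance components undefined, se set to 0")
    return(structure(list(mu = mu, var_trip = 0, var_haul = 0,
                          var_within = 0, se_mean = 0, n = 1L,
                          n_trips = 1L, n_hauls = 1L), class = "varcomp"))
  }
  haul_mean <- tapply(y, haul, mean)
  haul_n <- tapply(y, haul, length)
  haul_trip <- tapply(trip, haul, `[`, 1L)
  trip_n <- rowsum(as.vector(haul_n), as.vector(haul_trip))
  trip_mean <- rowsum(as.vector(haul_mean * haul_n),
                      as.vector(haul_trip)) / trip_n
  a <- nrow(trip_n)               # trips
  H <- length(haul_n)             # hauls
  trip_of_obs <- match(trip, rownames(trip_n))
  haul_of_obs <- match(haul, names(haul_mean))
  SSE <- sum((y - haul_mean[haul_of_obs])^2)
  SSH <- sum(haul_n * (haul_mean - trip_mean[match(as.vector(haul_trip),
                                                  rownames(trip_n))])^2)
  SST <- sum(trip_n * (trip_mean - mu)^2)
  var_within <- if (N - H > 0) SSE / (N - H) else 0
  # Searle's k coefficients for the unbalanced two-fold nested design
  sum_nh2_by_trip <- rowsum(as.vector(haul_n)^2, as.vector(haul_trip))
  s1 <- sum(sum_nh2_by_trip / trip_n)
  var_haul <- 0
  if (H - a > 0) {
    k1 <- (N - s1) / (H - a)
    var_haul <- (SSH / (H - a) - var_within) / k1
  }
  var_trip <- 0
  if (a - 1 > 0) {
    k2 <- (s1 - sum(haul_n^2) / N) / (a - 1)
    k3 <- (N - sum(trip_n^2) / N) / (a - 1)
    var_trip <- (SST / (a - 1) - var_within - k2 * var_haul) / k3
  }
  truncated <- c(trip = var_trip < 0, haul = var_haul < 0,
                 within = var_within < 0)
  if (any(truncated))
    warning(sprintf("negative variance component(s) truncated to 0: %s",
                    paste(names(truncated)[truncated], collapse = ", ")))
  var_trip <- max(0, var_trip)
  var_haul <- max(0, var_haul)
  var_within <- max(0, var_within)
  se_mean <- sqrt((var_trip * sum(trip_n^2) + var_haul * sum(haul_n^2) +
                     var_within * N) / N^2)
  structure(list(mu = mu, var_trip = var_trip, var_haul = var_haul,
                 var_within = var_within, se_mean = se_mean,
                 n = N, n_trips = a, n_hauls = H),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("Nested random-effects mean length\n")
  cat(sprintf("  mu = %.3f cm, se = %.3f cm (%d fish, %d hauls, %d trips)\n",
              x$mu, x$se_mean, x$n, x$n_hauls, x$n_trips))
  cat(sprintf("  variance components (cm^2): trip %.3f, haul %.3f, within %.3f\n",
              x$var_trip, x$var_haul, x$var_within))
  invisible(x)
}
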