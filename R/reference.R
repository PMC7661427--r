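# The deterministic iterative subsampling algorithm: remove one measurement
# from every important length class per iteration (never below its gamma
# floor), stop when the similarity conditions against the original fail, and
# return the previous subsample as the reference. Its L1 distance to the
# original is the admissible dissimilarity value (ADV).

#' Per-class minimum-count specification (gamma)
#'
#' Gamma encodes minimally required counts per length class in a reference
#' subsample, reflecting sampling-programme requirements (e.g. fish needed
#' for ageing) rather than statistics.
#'
#' @param mode One of:
#'   * `"zero"` - no floor, classes may be subsampled to zero;
#'   * `"absolute"` - a fixed count per class (capped at the class count);
#'   * `"fraction"` - a fraction `q` of the original class count, floored at
#'     the smallest integer `>= q * n_j` (a class keeps more than that share
#'     of its measurements);
#'   * `"adaptive"` - 20% of the class count for classes with at least 5
#'     measurements; sparse classes (`n_j < 5`) are frozen at their count.
#' @param value Count (`"absolute"`) or fraction in `[0, 1)` (`"fraction"`);
#'   ignored otherwise.
#' @return An object of class `gamma_spec`.
#' @export
gamma_spec <- function(mode = c("zero", "absolute", "fraction", "adaptive"),
                       value = NULL) {
  mode <- match.arg(mode)
  if (mode == "absolute") {
    if (is.null(value) || value < 0 || value != round(value))
      stop("absolute gamma needs a nonnegative integer `value`")
    value <- as.integer(value)
  } else if (mode == "fraction") {
    if (is.null(value) || value < 0 || value >= 1)
      stop("fractional gamma needs `value` in [0, 1)")
  } else value <- NULL
  structure(list(mode = mode, value = value), class = "gamma_spec")
}

#' @export
format.gamma_spec <- function(x, ...) {
  switch(x$mode,
         zero = "no floor (gamma = 0)",
         absolute = sprintf("at least %d per class", x$value),
         fraction = sprintf("at least %.0f%% of each class", 100 * x$value),
         adaptive = "20% of each class; classes with < 5 fish frozen")
}

#' @export
print.gamma_spec <- function(x, ...) {
  cat("Gamma floor:", format(x), "\n")
  invisible(x)
}

#' Per-class floors implied by a gamma specification
#'
#' @param orig The original `lfd`.
#' @param spec A [gamma_spec()].
#' @param range Important range (floors are computed on the restricted grid).
#' @return Named integer vector: class label -> minimum permitted count.
#' @examples
#' class_floors(lfd(c(`40` = 10, `41` = 3)), gamma_spec("adaptive"))
#' @export
class_floors <- function(orig, spec, range = NULL) {
  stopifnot(inherits(orig, "lfd"), inherits(spec, "gamma_spec"))
  r <- restrict(orig, range)
  n <- r$counts
  fl <- switch(spec$mode,
               zero = integer(length(n)),
               absolute = pmin(spec$value, n),
               fraction = as.integer(ceiling(spec$value * n)),
               adaptive = ifelse(n < 5L, n, as.integer(ceiling(0.2 * n))))
  stats::setNames(as.integer(fl), r$classes)
}

# Walk the deterministic candidate path. After i iterations every class
# sits at max(n_j - i, floor_j), so the path does not depend on (theta,
# epsilon); those parameters only pick the stopping step. Returns per-step
# condition statistics and L1 distances, shared by all (theta, epsilon)
# cells in grid studies. The walk stops once a step fails even the most
# permissive cell that will be consulted (theta_min, eps_max): no cell's
# stopping step can lie beyond it.
.reference_path <- function(pre, floors, theta_min = 0, eps_max = Inf) {
  x0 <- pre$counts
  n_max <- max(x0 - floors)
  if (n_max <= 0L) {
    return(list(n_steps = 0L, dim_ok = logical(0), max_shift = numeric(0),
                min_ratio = numeric(0), l1 = numeric(0), size = integer(0)))
  }
  dim_ok <- logical(n_max)
  max_shift <- numeric(n_max)
  min_ratio <- numeric(n_max)
  l1 <- numeric(n_max)
  size <- integer(n_max)
  F0 <- cumsum(x0) / sum(x0)
  n_steps <- n_max
  for (s in seq_len(n_max)) {
    cand <- pmax(x0 - s, floors)
    st <- .cond_stats(pre, cand)
    dim_ok[s] <- st$dim_ok
    max_shift[s] <- if (st$dim_ok) st$max_shift else NA_real_
    min_ratio[s] <- if (st$dim_ok) st$min_ratio else NA_real_
    l1[s] <- sum(abs(F0 - cumsum(cand) / sum(cand)))
    size[s] <- sum(cand)
    if (!st$dim_ok || st$max_shift > eps_max || st$min_ratio < theta_min) {
      n_steps <- s
      break
    }
  }
  keep <- seq_len(n_steps)
  list(n_steps = n_steps, dim_ok = dim_ok[keep], max_shift = max_shift[keep],
       min_ratio = min_ratio[keep], l1 = l1[keep], size = size[keep],
       exhausted = n_steps == n_max)
}

# First failing step for (theta, epsilon) given path statistics; 0 if the
# path was never entered. Returns list(accepted, reason).
.stop_from_path <- function(path, theta, epsilon) {
  if (path$n_steps == 0L)
    return(list(accepted = 0L, reason = "all_classes_at_floor"))
  fail1 <- !path$dim_ok
  fail2 <- !fail1 & path$max_shift > epsilon
  fail3 <- !fail1 & !fail2 & path$min_ratio < theta
  bad <- which(fail1 | fail2 | fail3)
  if (!length(bad))
    return(list(accepted = path$n_steps, reason = "all_classes_at_floor"))
  s <- bad[1L]
  reason <- if (fail1[s]) "mode_count_changed"
  else if (fail2[s]) "shift_exceeded"
  else "amplitude_ratio"
  list(accepted = s - 1L, reason = reason, failed_step = s)
}

#' Construct the reference subsample and its ADV
#'
#' Starting from the original sample restricted to the important range, each
#' iteration removes one measurement from every class whose count still
#' exceeds its gamma floor; the candidate is accepted while its robust
#' critical points satisfy the three similarity conditions against the
#' (fixed) original. On the first violation the previous subsample becomes
#' the reference; if no class can be thinned further the algorithm stops at
#' the floor. The ADV is the L1 CDF distance between the original and the
#' reference (all penalties vanish by construction). Classes outside the
#' important range are never touched.
#'
#' @param orig The original `lfd` (nonempty on `params$range`).
#' @param params An [adv_params()].
#' @return An object of class `reference_result`: `reference` (an `lfd` on
#'   the full original grid), `adv`, `iterations_accepted`, `removed_total`
#'   (within the important range), `stopping_reason` (one of
#'   `mode_count_changed`, `shift_exceeded`, `amplitude_ratio`,
#'   `all_classes_at_floor`), and `trace`, a per-iteration data.frame of
#'   candidate size and condition status.
#' @examples
#' x <- lfd(c(`1` = 5, `2` = 1, `3` = 5, `4` = 1, `5` = 5))
#' reference_subsample(x, adv_params(delta = 1, theta = 1, epsilon = 0))
#' @export
reference_subsample <- function(orig, params = adv_params()) {
  stopifnot(inherits(orig, "lfd"), inherits(params, "adv_params"))
  pre <- .orig_pre(orig, params)
  floors <- unname(class_floors(orig, params$gamma, params$range))
  path <- .reference_path(pre, floors, theta_min = params$theta,
                          eps_max = params$epsilon)
  stp <- .stop_from_path(path, params$theta, params$epsilon)
  i <- stp$accepted
  ref_counts <- pmax(pre$counts - i, floors)
  adv <- if (i == 0L) 0 else path$l1[i]
  # reassemble the full-grid reference (untouched outside the range)
  full <- orig$counts
  full[match(pre$grid, orig$classes)] <- ref_counts
  reference <- new_lfd(full, orig$classes, orig$origin, orig$class_width,
                       if (nzchar(orig$label)) paste(orig$label, "(reference)")
                       else "reference")
  n_eval <- min(if (is.null(stp$failed_step)) path$n_steps else stp$failed_step,
                path$n_steps)
  trace <- if (n_eval > 0L) {
    data.frame(
      iteration = seq_len(n_eval),
      size = path$size[seq_len(n_eval)],
      cond_counts = path$dim_ok[seq_len(n_eval)],
      cond_shift = ifelse(path$dim_ok[seq_len(n_eval)],
                          path$max_shift[seq_len(n_eval)] <= params$epsilon, NA),
      cond_amplitude = ifelse(path$dim_ok[seq_len(n_eval)],
                              path$min_ratio[seq_len(n_eval)] >= params$theta, NA),
      accepted = seq_len(n_eval) <= i
    )
  } else {
    data.frame(iteration = integer(0), size = integer(0),
               cond_counts = logical(0), cond_shift = logical(0),
               cond_amplitude = logical(0), accepted = logical(0))
  }
  structure(
    list(reference = reference, adv = adv, iterations_accepted = i,
         removed_total = sum(pre$counts) - sum(ref_counts),
         stopping_reason = stp$reason, trace = trace,
         params = params),
    class = "reference_result"
  )
}

#' Admissible dissimilarity value (ADV)
#'
#' The L1 CDF distance between the original sample and its reference
#' subsample; the admissibility threshold for candidate subsamples.
#'
#' @inheritParams reference_subsample
#' @return Nonnegative scalar.
#' @export
adv <- function(orig, params = adv_params()) {
  reference_subsample(orig, params)$adv
}

#' Is a subsample admissible with respect to the original sample?
#'
#' A subsample is representative (admissible) when its penalized
#' dissimilarity to the original does not exceed the ADV.
#'
#' @param orig,sub `lfd` objects.
#' @param params An [adv_params()].
#' @return A list: `admissible` (logical), `D`, `adv`.
#' @export
is_admissible <- function(orig, sub, params = adv_params()) {
  D <- dissimilarity(orig, sub, params)$total_D
  a <- adv(orig, params)
  list(admissible = D <= a, D = D, adv = a)
}

#' @export
print.reference_result <- function(x, ...) {
  cat("Reference subsample\n")
  cat(sprintf("  iterations accepted: %d\n", x$iterations_accepted))
  cat(sprintf("  removed (important range): %d\n", x$removed_total))
  cat(sprintf("  stopping reason: %s\n", x$stopping_reason))
  cat(sprintf("  ADV: %.6f\n", x$adv))
  invisible(x)
}
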