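# Penalized dissimilarity between an original LFD and a subsample LFD:
# the L1 (1-Wasserstein) distance between empirical class CDFs plus penalty
# terms for violating the three similarity conditions (equal numbers of
# robust critical points; shifts within epsilon; amplitude ratios >= theta).

#' Parameters of the subsampling / dissimilarity algorithm
#'
#' @param delta Smoothing bandwidth in cm used to decide robustness of
#'   critical points (default 5, suitable for large gadoids).
#' @param theta Amplitude preservation ratio in (0, 1]: consecutive
#'   critical-point amplitude differences in the subsample must be at least
#'   `theta` times the original ones (default 0.9).
#' @param epsilon Permitted shift of critical points in cm (default 0).
#' @param gamma A [gamma_spec()] giving per-class minimum counts for the
#'   reference-subsample algorithm (default none, `gamma_spec("zero")`).
#' @param range Important length classes as [important_range()] or
#'   `c(low, high)`; `NULL` means all classes present.
#' @param c1,c2,c3 Nonnegative penalty constants for violating conditions
#'   (1)-(3); defaults 10, 2, 1 set a hierarchy with the count mismatch
#'   penalized hardest.
#' @param amplitude_mode `"pointwise"` (amplitudes are counts at the robust
#'   critical classes, the default) or `"cdf_mass"` (amplitude of a
#'   consecutive pair is the class mass between the two critical points).
#' @param p Minkowski order for [lp_distance()] (default 1, the L1 /
#'   1-Wasserstein distance).
#' @return An object of class `adv_params`.
#' @export
adv_params <- function(delta = 5, theta = 0.9, epsilon = 0,
                       gamma = gamma_spec("zero"), range = NULL,
                       c1 = 10, c2 = 2, c3 = 1,
                       amplitude_mode = c("pointwise", "cdf_mass"), p = 1) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1)
    stop("`theta` must lie in (0, 1]")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("`epsilon` must be >= 0")
  if (!is.numeric(p) || length(p) != 1L || p < 1) stop("`p` must be >= 1")
  if (any(c(c1, c2, c3) < 0)) stop("penalty constants must be nonnegative")
  if (!inherits(gamma, "gamma_spec")) stop("`gamma` must be a gamma_spec()")
  structure(
    list(delta = as.integer(delta), theta = theta, epsilon = epsilon,
         gamma = gamma, range = .as_range(range),
         c1 = c1, c2 = c2, c3 = c3,
         amplitude_mode = amplitude_mode, p = p),
    class = "adv_params"
  )
}

#' @export
print.adv_params <- function(x, ...) {
  cat(sprintf(
    "ADV algorithm parameters\n  delta = %d cm, theta = %g, epsilon = %g cm\n",
    x$delta, x$theta, x$epsilon))
  cat(sprintf("  gamma: %s\n", format(x$gamma)))
  cat(sprintf("  range: %s\n",
              if (is.null(x$range)) "all classes"
              else sprintf("[%d, %d] cm", x$range$low, x$range$high)))
  cat(sprintf("  penalties c1 = %g, c2 = %g, c3 = %g; amplitudes %s; p = %g\n",
              x$c1, x$c2, x$c3, x$amplitude_mode, x$p))
  invisible(x)
}

#' Minkowski distance between two empirical CDFs
#'
#' `sum(|F - G|^p)^(1/p)` over a shared class grid; with `p = 1` this is the
#' Manhattan / 1-Wasserstein distance, the area between the two step CDFs.
#'
#' @param F,G Objects of class `lfd_cdf` on identical class grids (align the
#'   samples over a shared important range first; see [dissimilarity()]).
#' @param p Minkowski order, `>= 1`.
#' @return Nonnegative scalar; 0 iff `F` and `G` agree on the grid.
#' @export
lp_distance <- function(F, G, p = 1) {
  stopifnot(inherits(F, "lfd_cdf"), inherits(G, "lfd_cdf"))
  if (length(F$classes) != length(G$classes) || any(F$classes != G$classes))
    stop("CDFs are defined on different class grids")
  if (p < 1) stop("`p` must be >= 1")
  sum(abs(F$values - G$values)^p)^(1 / p)
}

# Align two LFDs on the union dense grid within `range` and return their
# count vectors (zero where a sample has no class). CDF values for classes a
# sample never reached are implied by cumulative sums carried forward.
.align_counts <- function(orig, sub, range = NULL) {
  ro <- restrict(orig, range)
  rs <- restrict(sub, range)
  if (!length(ro$counts) || sum(ro$counts) == 0L)
    stop("original sample has no mass in important range")
  if (!length(rs$counts) || sum(rs$counts) == 0L)
    stop("subsample has no mass in important range")
  lo <- min(ro$classes[1L], rs$classes[1L])
  hi <- max(ro$classes[length(ro$classes)], rs$classes[length(rs$classes)])
  grid <- seq.int(lo, hi, by = ro$class_width)
  xo <- integer(length(grid)); xo[match(ro$classes, grid)] <- ro$counts
  xs <- integer(length(grid)); xs[match(rs$classes, grid)] <- rs$counts
  list(grid = grid, orig = xo, sub = xs)
}

.l1_counts <- function(xo, xs, p = 1) {
  Fo <- cumsum(xo) / sum(xo)
  Fs <- cumsum(xs) / sum(xs)
  sum(abs(Fo - Fs)^p)^(1 / p)
}

# Amplitude values used in condition (3) / the amplitude penalty, for one
# sample's merged critical sequence `pts` over counts x on classes cls.
#  - pointwise: count at each critical class; consecutive differences are
#    taken by the caller.
#  - cdf_mass: mass (sum of counts) in (pts[i-1], pts[i]] for i >= 2; the
#    "difference" for pair i is that interval mass itself.
.amplitude_pairs <- function(pts, x, cls, mode) {
  k <- length(pts)
  if (k < 2L) return(numeric(0))
  if (mode == "pointwise") {
    a <- x[match(pts, cls)]
    a[is.na(a)] <- 0
    abs(diff(a))
  } else {
    cum <- cumsum(x)
    idx <- findInterval(pts, cls)   # pts lie on cls for own sample; robust otherwise
    cs <- c(0, cum)[idx + 1L]
    abs(diff(cs))
  }
}

# Condition statistics between a fixed original (precomputed) and a
# candidate subsample given as a count vector on the SAME restricted grid.
# Returns dim_ok, max within-type shift, merged shifts, amplitude ratios.
.cond_stats <- function(pre, xs) {
  cp <- .robust_cp(xs, pre$grid, pre$delta, pre$origin)
  dim_ok <- length(cp$modes) == length(pre$cp$modes) &&
    length(cp$antimodes) == length(pre$cp$antimodes)
  if (!dim_ok) {
    return(list(dim_ok = FALSE, cp = cp, max_shift = NA_real_,
                merged_shift = NULL, ratios = NULL, min_ratio = NA_real_))
  }
  shift_m <- abs(cp$modes - pre$cp$modes)
  shift_a <- abs(cp$antimodes - pre$cp$antimodes)
  max_shift <- if (length(shift_m) + length(shift_a))
    max(c(shift_m, shift_a)) else 0
  merged_shift <- abs(cp$merged - pre$cp$merged)
  num <- .amplitude_pairs(cp$merged, xs, pre$grid, pre$amplitude_mode)
  ratios <- num[pre$amp_keep] / pre$amp_den[pre$amp_keep]
  min_ratio <- if (length(ratios)) min(ratios) else Inf
  list(dim_ok = TRUE, cp = cp, max_shift = max_shift,
       merged_shift = merged_shift, ratios = ratios, min_ratio = min_ratio)
}

# Precompute everything about the original needed to score candidates fast.
.orig_pre <- function(orig, params) {
  ro <- restrict(orig, params$range)
  if (!length(ro$counts) || sum(ro$counts) == 0L)
    stop("original sample has no mass in important range")
  cp <- .robust_cp(ro$counts, ro$classes, params$delta, ro$origin)
  den <- .amplitude_pairs(cp$merged, ro$counts, ro$classes,
                          params$amplitude_mode)
  keep <- den > 0
  list(grid = ro$classes, counts = ro$counts, origin = ro$origin,
       delta = params$delta, cp = cp,
       amplitude_mode = params$amplitude_mode,
       amp_den = den, amp_keep = keep,
       n_skipped_pairs = sum(!keep))
}

# Map a subsample lfd onto the original's restricted grid (classes outside
# the original's restricted span are not representable; callers needing the
# union grid use .align_counts instead).
.sub_on_grid <- function(pre, sub, range) {
  rs <- restrict(sub, range)
  if (!length(rs$counts) || sum(rs$counts) == 0L)
    stop("subsample has no mass in important range")
  lo <- min(pre$grid[1L], rs$classes[1L])
  hi <- max(pre$grid[length(pre$grid)], rs$classes[length(rs$classes)])
  grid <- seq.int(lo, hi, by = rs$class_width)
  xo <- integer(length(grid)); xo[match(pre$grid, grid)] <- pre$counts
  xs <- integer(length(grid)); xs[match(rs$classes, grid)] <- rs$counts
  list(grid = grid, orig = xo, sub = xs)
}

#' Check the three similarity conditions between original and subsample
#'
#' Condition (1): equal numbers of robust modes and of robust antimodes.
#' Condition (2): pairing modes with modes and antimodes with antimodes in
#' ascending order, every location shift is at most `epsilon` cm. Condition
#' (3): for every consecutive pair in the merged critical sequence, the
#' subsample amplitude difference is at least `theta` times the original
#' one. Conditions (2) and (3) are only defined when (1) holds (`NA`
#' otherwise). Consecutive pairs whose original amplitude difference is zero
#' are skipped with a warning (the ratio is undefined).
#'
#' @param orig,sub `lfd` objects (the original sample and a subsample).
#' @param params An [adv_params()].
#' @return A list: logical `conditions` (length 3, possibly `NA`),
#'   `orig_points` / `sub_points` (`critical_points`), `shifts` (within-type
#'   absolute shifts), `ratios` (amplitude ratios over consecutive merged
#'   pairs), `skipped_pairs`.
#' @export
check_conditions <- function(orig, sub, params = adv_params()) {
  stopifnot(inherits(orig, "lfd"), inherits(sub, "lfd"),
            inherits(params, "adv_params"))
  pre <- .orig_pre(orig, params)
  al <- .sub_on_grid(pre, sub, params$range)
  pre2 <- pre; pre2$grid <- al$grid; pre2$counts <- al$orig
  st <- .cond_stats(pre2, al$sub)
  if (pre$n_skipped_pairs > 0)
    warning(sprintf(
      "%d consecutive critical pair(s) skipped: zero amplitude difference in the original",
      pre$n_skipped_pairs))
  cond1 <- st$dim_ok
  cond2 <- if (cond1) st$max_shift <= params$epsilon else NA
  cond3 <- if (cond1) st$min_ratio >= params$theta else NA
  sub_cp <- structure(
    list(modes = st$cp$modes, antimodes = st$cp$antimodes,
         merged = st$cp$merged, type = st$cp$type,
         amplitudes_at = stats::setNames(st$cp$amp, st$cp$merged),
         delta = params$delta),
    class = "critical_points")
  orig_cp <- structure(
    list(modes = pre$cp$modes, antimodes = pre$cp$antimodes,
         merged = pre$cp$merged, type = pre$cp$type,
         amplitudes_at = stats::setNames(pre$cp$amp, pre$cp$merged),
         delta = params$delta),
    class = "critical_points")
  list(conditions = c(counts = cond1, shift = cond2, amplitude = cond3),
       orig_points = orig_cp, sub_points = sub_cp,
       shifts = if (cond1) c(abs(st$cp$modes - pre$cp$modes),
                             abs(st$cp$antimodes - pre$cp$antimodes)) else NULL,
       ratios = st$ratios, skipped_pairs = pre$n_skipped_pairs)
}

# Core of dissimilarity(): penalties from condition statistics.
.penalties <- function(st, params) {
  if (!st$dim_ok)
    return(c(dim = params$c1, shift = 0, amplitude = 0))
  shift <- params$c2 * sum(pmax(0, st$merged_shift - params$epsilon))
  ampl <- params$c3 * sum(pmax(0, params$theta - st$ratios))
  c(dim = 0, shift = shift, amplitude = ampl)
}

#' Penalized dissimilarity D between an original sample and a subsample
#'
#' `D = L1(F, G) + c1 * [count mismatch] + c2 * sum(max(0, |v_i - V_i| - epsilon))
#'  + c3 * sum(max(0, theta - amplitude ratio))`, where the shift and
#' amplitude sums run over the merged critical sequences and apply only when
#' the numbers of robust critical points match. `D = 0` iff the subsample
#' equals the original on the important range; `D` equals the plain L1
#' distance iff all three similarity conditions hold.
#'
#' @inheritParams check_conditions
#' @return An object of class `dissimilarity`: `l1`, `penalty_dim`,
#'   `penalty_shift`, `penalty_amplitude`, `total_D`, `condition_flags`,
#'   `paired_points` (data.frame of merged critical pairs, when defined).
#' @examples
#' a <- lfd(c(`1` = 5, `2` = 1, `3` = 5))
#' b <- lfd(c(`1` = 5, `2` = 5, `3` = 5))
#' dissimilarity(a, b, adv_params(delta = 1))
#' @export
dissimilarity <- function(orig, sub, params = adv_params()) {
  stopifnot(inherits(orig, "lfd"), inherits(sub, "lfd"),
            inherits(params, "adv_params"))
  pre <- .orig_pre(orig, params)
  al <- .sub_on_grid(pre, sub, params$range)
  pre2 <- pre; pre2$grid <- al$grid; pre2$counts <- al$orig
  st <- .cond_stats(pre2, al$sub)
  l1 <- .l1_counts(al$orig, al$sub, params$p)
  pen <- .penalties(st, params)
  cond1 <- st$dim_ok
  flags <- c(counts = cond1,
             shift = if (cond1) st$max_shift <= params$epsilon else NA,
             amplitude = if (cond1) st$min_ratio >= params$theta else NA)
  paired <- if (cond1 && length(pre$cp$merged)) {
    data.frame(original = pre$cp$merged, subsample = st$cp$merged,
               type = pre$cp$type, shift = st$merged_shift)
  } else NULL
  structure(
    list(l1 = l1, penalty_dim = unname(pen["dim"]),
         penalty_shift = unname(pen["shift"]),
         penalty_amplitude = unname(pen["amplitude"]),
         total_D = l1 + sum(pen),
         condition_flags = flags,
         paired_points = paired,
         skipped_pairs = pre$n_skipped_pairs),
    class = "dissimilarity"
  )
}

#' @export
print.dissimilarity <- function(x, ...) {
  cat("Penalized LFD dissimilarity\n")
  cat(sprintf("  L1 distance:        %.6f\n", x$l1))
  cat(sprintf("  penalty (counts):   %.6f\n", x$penalty_dim))
  cat(sprintf("  penalty (shift):    %.6f\n", x$penalty_shift))
  cat(sprintf("  penalty (amplitude):%.6f\n", x$penalty_amplitude))
  cat(sprintf("  total D:            %.6f\n", x$total_D))
  fl <- x$condition_flags
  cat(sprintf("  conditions: counts %s, shift %s, amplitude %s\n",
              fl[1], fl[2], fl[3]))
  invisible(x)
}
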