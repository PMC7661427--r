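# Mode/antimode detection and robust critical points under bandwidth
# smoothing. Modes are detected against a zero-padded grid (a boundary class
# can carry a mode); antimodes are interior-only, so empty tails never count
# as gaps. For runs of equal counts the first (smallest) class represents the
# run, for modes and antimodes alike.

# Run-compressed local extrema of a count vector. Returns positions (indices
# into x) of mode and antimode classes.
.run_extrema <- function(x) {
  r <- rle(as.numeric(x))
  v <- r$values
  n <- length(v)
  starts <- cumsum(c(1L, r$lengths[-n]))
  prev <- c(0, v[-n])   # zero pad outside the grid
  nxt <- c(v[-1L], 0)
  is_mode <- v > prev & v > nxt
  is_anti <- logical(n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    is_anti[i] <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  }
  list(modes = starts[is_mode], antimodes = starts[is_anti])
}

# Robust critical points on a dense count vector `x` over classes `cls`
# (width 1 assumed for the fine grid). Leading/trailing zero classes are
# trimmed first so results do not depend on how far the stored grid extends.
# Steps: fine-grid extrema; delta-smoothed extrema; a fine mode is robust iff
# it falls in a smoothed-mode bin and dominates (max frequency, ties to the
# smallest class) the fine modes in that bin; symmetrically for antimodes
# with minimal frequency; finally modes with frequency <= 1% of the largest
# fine-mode frequency are dropped (no such filter for antimodes).
.robust_cp <- function(x, cls, delta, origin = 0L) {
  empty <- list(modes = integer(0), antimodes = integer(0),
                merged = integer(0), type = character(0),
                amp = numeric(0), f_modes = numeric(0), f_antimodes = numeric(0))
  nz <- which(x > 0L)
  if (!length(nz)) return(empty)
  sel <- nz[1L]:nz[length(nz)]
  x <- x[sel]
  cls <- cls[sel]
  e1 <- .run_extrema(x)
  M <- cls[e1$modes]; fM <- x[e1$modes]
  A <- cls[e1$antimodes]; fA <- x[e1$antimodes]
  if (delta > 1L) {
    b <- (cls - origin) %/% delta
    sums <- rowsum(x, b)
    ub <- as.integer(rownames(sums))
    es <- .run_extrema(as.vector(sums))
    mode_bins <- ub[es$modes]
    anti_bins <- ub[es$antimodes]
    if (length(M)) {
      bm <- (M - origin) %/% delta
      keep <- vapply(mode_bins, function(bb) {
        cand <- which(bm == bb)
        if (!length(cand)) return(NA_integer_)
        cand[which.max(fM[cand])]   # ties -> smallest class (first index)
      }, integer(1))
      keep <- keep[!is.na(keep)]
      M <- M[keep]; fM0 <- fM; fM <- fM[keep]
    } else fM0 <- fM
    if (length(A)) {
      ba <- (A - origin) %/% delta
      keep <- vapply(anti_bins, function(bb) {
        cand <- which(ba == bb)
        if (!length(cand)) return(NA_integer_)
        cand[which.min(fA[cand])]
      }, integer(1))
      keep <- keep[!is.na(keep)]
      A <- A[keep]; fA <- fA[keep]
    }
  } else {
    fM0 <- fM
  }
  # 1% frequency rule, relative to the largest fine-grid mode frequency
  if (length(M) && length(fM0)) {
    ok <- fM > 0.01 * max(fM0)
    M <- M[ok]; fM <- fM[ok]
  }
  merged <- sort(c(M, A))
  type <- ifelse(merged %in% M, "mode", "antimode")
  amp <- x[match(merged, cls)]
  list(modes = M, antimodes = A, merged = merged, type = type,
       amp = as.numeric(amp), f_modes = as.numeric(fM),
       f_antimodes = as.numeric(fA))
}

#' Local modes and antimodes of an LFD
#'
#' A class is a mode if adjacent classes have lower counts, an antimode if
#' adjacent classes have higher counts; ties are resolved to the first
#' (smallest) class of an equal-count run. The grid is zero-padded for mode
#' detection, so boundary classes can be modes; antimodes are interior only.
#'
#' @param x An `lfd` (nonempty).
#' @return A list with integer vectors `modes` and `antimodes` (class labels).
#' @examples
#' local_extrema(lfd(c(`1` = 1, `2` = 3, `3` = 1, `4` = 4, `5` = 2)))
#' @export
local_extrema <- function(x) {
  stopifnot(inherits(x, "lfd"))
  if (!length(x$counts) || all(x$counts == 0L)) stop("empty LFD")
  nz <- which(x$counts > 0L)
  sel <- nz[1L]:nz[length(nz)]
  e <- .run_extrema(x$counts[sel])
  list(modes = x$classes[sel][e$modes], antimodes = x$classes[sel][e$antimodes])
}

#' Robust critical points of an LFD under bandwidth smoothing
#'
#' A 1-cm mode is robust when it survives smoothing with bandwidth `delta`:
#' its class must fall into a smoothed-histogram mode bin and it must be the
#' dominating (highest-frequency) 1-cm mode within that bin (ties to the
#' smallest class). Antimodes are treated symmetrically with minimal
#' frequency. Modes with frequency at or below 1% of the largest 1-cm mode
#' frequency are discarded as noise; antimodes carry no frequency filter.
#'
#' @param x An `lfd` with 1-cm classes.
#' @param delta Smoothing bandwidth in cm (a multiple of the class width;
#'   `delta` equal to the class width applies no smoothing).
#' @param range Important range, or `NULL` for all classes.
#' @return An object of class `critical_points`: ascending `modes` and
#'   `antimodes`, their sorted `merged` sequence with `type` tags, and
#'   `amplitudes_at`, the count at each merged class.
#' @examples
#' x <- lfd(c(`1` = 1, `2` = 5, `3` = 4, `4` = 6, `5` = 2, `6` = 1))
#' robust_critical_points(x, delta = 2)
#' @export
robust_critical_points <- function(x, delta, range = NULL) {
  stopifnot(inherits(x, "lfd"))
  r <- restrict(x, range)
  if (!length(r$counts) || all(r$counts == 0L))
    stop("no mass in important range")
  delta <- as.integer(delta)
  if (delta < r$class_width || delta %% r$class_width != 0L)
    stop("`delta` must be a multiple of the class width")
  cp <- .robust_cp(r$counts, r$classes, delta, r$origin)
  structure(
    list(modes = cp$modes, antimodes = cp$antimodes, merged = cp$merged,
         type = cp$type,
         amplitudes_at = stats::setNames(cp$amp, cp$merged),
         delta = delta),
    class = "critical_points"
  )
}

#' @export
print.critical_points <- function(x, ...) {
  cat(sprintf("Robust critical points (bandwidth %d cm)\n", x$delta))
  cat("  modes:    ", if (length(x$modes)) paste(x$modes, collapse = ", ") else "(none)", "\n")
  cat("  antimodes:", if (length(x$antimodes)) paste(x$antimodes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
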