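# Length-frequency distribution (LFD) objects: dense per-class counts on an
# integer class grid, the carrier for everything downstream (critical points,
# CDFs, distances).

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

new_lfd <- function(counts, classes, origin = 0, class_width = 1L, label = "") {
  structure(
    list(
      classes = as.integer(classes),
      counts = as.integer(counts),
      origin = as.integer(origin),
      class_width = as.integer(class_width),
      label = as.character(label)
    ),
    class = "lfd"
  )
}

#' Construct a length-frequency distribution from per-class counts
#'
#' An `lfd` stores raised (or raw) fish counts on a dense, contiguous grid of
#' length classes. Interior zero-count classes are kept explicitly so that
#' gaps (antimodes at empty classes) remain detectable.
#'
#' @param counts Nonnegative integer counts, one per class. May be named by
#'   class lower bound; otherwise supply `classes`.
#' @param classes Integer class lower bounds (cm), each equal to
#'   `origin + k * class_width`. Defaults to the names of `counts`.
#' @param origin Bin origin in cm (default 0, the convention used throughout).
#' @param class_width Class width in cm (integer, >= 1).
#' @param label Free-text label.
#' @return An object of class `lfd` with fields `classes`, `counts`,
#'   `origin`, `class_width`, `label`.
#' @examples
#' lfd(c(`40` = 2, `41` = 1, `43` = 1))
#' @export
lfd <- function(counts, classes = NULL, origin = 0, class_width = 1, label = "") {
  if (is.null(classes)) {
    if (is.null(names(counts)) && length(counts) > 0)
      stop("supply `classes` or a named `counts` vector")
    classes <- as.integer(names(counts))
  }
  class_width <- as.integer(class_width)
  origin <- as.integer(origin)
  if (length(class_width) != 1L || is.na(class_width) || class_width < 1L)
    stop("`class_width` must be a single integer >= 1")
  if (length(counts) != length(classes))
    stop("`counts` and `classes` lengths differ")
  if (length(counts) == 0L)
    return(new_lfd(integer(0), integer(0), origin, class_width, label))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any((classes - origin) %% class_width != 0))
    stop("classes must sit on the grid origin + k * class_width")
  o <- order(classes)
  classes <- as.integer(classes[o])
  counts <- counts[o]
  if (anyDuplicated(classes)) stop("duplicated classes")
  # densify: materialize interior zero classes
  grid <- seq.int(classes[1L], classes[length(classes)], by = class_width)
  dense <- integer(length(grid))
  dense[match(classes, grid)] <- as.integer(counts)
  new_lfd(dense, grid, origin, class_width, label)
}

#' Tally raw length measurements into a length-frequency distribution
#'
#' Lengths are rounded to the nearest centimetre (ties away from zero, the
#' usual market-sampling convention) and tallied on a dense class grid from
#' the smallest to the largest observed class.
#'
#' @param lengths Numeric lengths in cm (all `>= origin`). May be empty.
#' @param class_width Class width in cm (integer >= 1).
#' @param origin Bin origin in cm.
#' @param label Free-text label.
#' @return An `lfd`; empty input gives an empty `lfd` with total 0.
#' @examples
#' build_lfd(c(40, 40, 41, 43))
#' @export
build_lfd <- function(lengths, class_width = 1, origin = 0, label = "") {
  class_width <- as.integer(class_width)
  origin <- as.integer(origin)
  if (length(class_width) != 1L || is.na(class_width) || class_width < 1L)
    stop("`class_width` must be a single integer >= 1")
  if (length(lengths) == 0L)
    return(new_lfd(integer(0), integer(0), origin, class_width, label))
  if (any(!is.finite(lengths))) stop("non-finite lengths")
  l <- round_half_up(lengths)
  if (any(l < origin))
    stop("lengths below the bin origin (negative or sub-origin measurements)")
  cls <- origin + ((l - origin) %/% class_width) * class_width
  grid <- seq.int(min(cls), max(cls), by = class_width)
  counts <- tabulate(match(cls, grid), nbins = length(grid))
  new_lfd(counts, grid, origin, class_width, label)
}

#' Total number of fish in an LFD
#' @param x An `lfd`.
#' @return Integer total count.
#' @export
lfd_total <- function(x) {
  stopifnot(inherits(x, "lfd"))
  sum(x$counts)
}

#' Rebin an LFD to a coarser bandwidth
#'
#' Classes are pooled into half-open bins `[origin + k*delta, origin + (k+1)*delta)`.
#' The bandwidth acts as a smoothing parameter: coarser bins wash out spurious
#' 1-cm spikes and gaps while preserving the total count.
#'
#' @param x An `lfd`.
#' @param delta Target bandwidth in cm; must be a multiple of `x$class_width`.
#' @return An `lfd` with `class_width = delta`.
#' @examples
#' rebin(lfd(c(`1` = 1, `2` = 5, `3` = 4, `4` = 6, `5` = 2, `6` = 1)), 2)
#' @export
rebin <- function(x, delta) {
  stopifnot(inherits(x, "lfd"))
  if (length(delta) != 1L || is.na(delta) || delta != round(delta) ||
      delta < x$class_width || delta %% x$class_width != 0)
    stop("`delta` must be a multiple of the class width, and at least as large")
  delta <- as.integer(delta)
  if (delta == x$class_width || length(x$counts) == 0L) {
    x$class_width <- delta
    return(x)
  }
  b <- (x$classes - x$origin) %/% delta
  sums <- rowsum(x$counts, b)
  ub <- as.integer(rownames(sums))
  new_lfd(as.vector(sums), x$origin + ub * delta, x$origin, delta, x$label)
}

#' Define the important length-class interval
#'
#' The interval of length classes over which CDFs, critical points and the
#' dissimilarity are evaluated; classes outside it are ignored (e.g. very
#' small or very large fish). Closed on class labels at both ends.
#'
#' @param low,high Inclusive bounds in cm, `low <= high`.
#' @return An object of class `important_range`.
#' @export
important_range <- function(low, high) {
  low <- as.integer(low); high <- as.integer(high)
  if (length(low) != 1L || length(high) != 1L || is.na(low) || is.na(high))
    stop("`low` and `high` must be single integers")
  if (low > high) stop("`low` must not exceed `high`")
  structure(list(low = low, high = high), class = "important_range")
}

.as_range <- function(range) {
  if (is.null(range)) return(NULL)
  if (inherits(range, "important_range")) return(range)
  if (is.numeric(range) && length(range) == 2L)
    return(important_range(range[1L], range[2L]))
  stop("`range` must be NULL, an important_range, or c(low, high)")
}

#' Restrict an LFD to an important range
#'
#' Classes outside `[low, high]` are dropped; interior zero classes are
#' preserved but the grid is re-trimmed to the support inside the window
#' (zero-count ends left by the cut are removed).
#'
#' @param x An `lfd`.
#' @param range An [important_range()], `c(low, high)`, or `NULL` (no-op).
#' @return An `lfd` covering only classes within the range (possibly empty).
#' @export
restrict <- function(x, range = NULL) {
  stopifnot(inherits(x, "lfd"))
  range <- .as_range(range)
  if (is.null(range)) return(x)
  keep <- x$classes >= range$low & x$classes <= range$high
  counts <- x$counts[keep]
  classes <- x$classes[keep]
  nz <- which(counts > 0L)
  if (length(nz)) {
    sel <- nz[1L]:nz[length(nz)]
    counts <- counts[sel]
    classes <- classes[sel]
  } else {
    counts <- integer(0)
    classes <- integer(0)
  }
  new_lfd(counts, classes, x$origin, x$class_width, x$label)
}

#' Empirical CDF of an LFD over the important range
#'
#' Cumulative class counts normalized by the total count inside the range,
#' so the final value is exactly 1.
#'
#' @param x An `lfd`.
#' @param range Important range (or `NULL` for all classes).
#' @return An object of class `lfd_cdf` with fields `classes`, `values`,
#'   `total`.
#' @export
lfd_cdf <- function(x, range = NULL) {
  r <- restrict(x, range)
  tot <- sum(r$counts)
  if (tot == 0L) stop("no mass in important range")
  structure(
    list(classes = r$classes, values = cumsum(r$counts) / tot, total = tot),
    class = "lfd_cdf"
  )
}

#' @export
print.lfd <- function(x, ...) {
  tot <- sum(x$counts)
  cat(sprintf(
    "Length-frequency distribution%s\n  %d classes (width %d cm, origin %d), total count %d\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$classes), x$class_width, x$origin, tot
  ))
  if (length(x$classes)) {
    cat(sprintf("  span: [%d, %d] cm\n", x$classes[1L],
                x$classes[length(x$classes)] + x$class_width - 1L))
  }
  invisible(x)
}

#' @export
print.important_range <- function(x, ...) {
  cat(sprintf("Important length classes: [%d, %d] cm\n", x$low, x$high))
  invisible(x)
}

#' @export
print.lfd_cdf <- function(x, ...) {
  cat(sprintf("Empirical LFD CDF on %d classes (total %d)\n",
              length(x$classes), x$total))
  invisible(x)
}

#' @export
plot.lfd <- function(x, ..., main = x$label, xlab = "Length class (cm)",
                     ylab = "Count") {
  if (!length(x$classes)) {
    plot.new()
    return(invisible(x))
  }
  graphics::barplot(x$counts, names.arg = x$classes, space = 0,
                    main = main, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Convert an LFD to a data frame
#' @param x An `lfd`.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return A data.frame with columns `class` and `count`.
#' @export
as.data.frame.lfd <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(class = x$classes, count = x$counts)
}
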