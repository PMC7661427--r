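# Independent brute-force oracles, written as literal enumeration with
# explicit loops so they share no code path with the package internals.

# Trim zero classes at both ends of a counts/classes pair.
oracle_trim <- function(counts, classes) {
  nz <- which(counts > 0)
  if (!length(nz)) return(list(counts = integer(0), classes = integer(0)))
  sel <- nz[1]:nz[length(nz)]
  list(counts = counts[sel], classes = classes[sel])
}

# Literal mode/antimode enumeration: for every class, scan left and right
# past equal-count runs; a mode needs strictly lower values on both sides
# (zero outside the grid), an antimode strictly higher values on both sides
# and both neighbours inside the grid; only the first class of an
# equal-count run qualifies.
oracle_extrema <- function(counts, classes) {
  tr <- oracle_trim(counts, classes)
  x <- tr$counts; cls <- tr$classes
  K <- length(x)
  modes <- integer(0); antimodes <- integer(0)
  for (j in seq_len(K)) {
    v <- x[j]
    if (j > 1 && x[j - 1] == v) next  # not first of its run
    i <- j - 1
    while (i >= 1 && x[i] == v) i <- i - 1
    left <- if (i >= 1) x[i] else NA
    r <- j + 1
    while (r <= K && x[r] == v) r <- r + 1
    right <- if (r <= K) x[r] else NA
    left_mode <- if (is.na(left)) 0 else left
    right_mode <- if (is.na(right)) 0 else right
    if (v > left_mode && v > right_mode) modes <- c(modes, cls[j])
    if (!is.na(left) && !is.na(right) && v < left && v < right)
      antimodes <- c(antimodes, cls[j])
  }
  list(modes = modes, antimodes = antimodes)
}

# Literal robustness check: a fine-grid mode is robust iff its smoothing bin
# is a mode of the smoothed histogram and it has the largest frequency among
# fine modes in that bin (first/smallest class on ties), then the 1% rule;
# antimodes symmetric with minimal frequency and no frequency rule.
oracle_robust_cp <- function(counts, classes, delta, origin = 0) {
  tr <- oracle_trim(counts, classes)
  x <- tr$counts; cls <- tr$classes
  if (!length(x)) return(list(modes = integer(0), antimodes = integer(0)))
  fine <- oracle_extrema(x, cls)
  if (delta <= 1) {
    M <- fine$modes; A <- fine$antimodes
  } else {
    bins <- floor((cls - origin) / delta)
    ubins <- sort(unique(bins))
    sm <- integer(length(ubins))
    for (k in seq_along(ubins))
      for (j in seq_along(cls))
        if (bins[j] == ubins[k]) sm[k] <- sm[k] + x[j]
    sm_ext <- oracle_extrema(sm, ubins)
    M <- integer(0)
    for (bb in sm_ext$modes) {
      best <- NA; bestf <- -Inf
      for (m in fine$modes) {
        if (floor((m - origin) / delta) == bb) {
          f <- x[which(cls == m)]
          if (f > bestf) { best <- m; bestf <- f }
        }
      }
      if (!is.na(best)) M <- c(M, best)
    }
    A <- integer(0)
    for (bb in sm_ext$antimodes) {
      best <- NA; bestf <- Inf
      for (a in fine$antimodes) {
        if (floor((a - origin) / delta) == bb) {
          f <- x[which(cls == a)]
          if (f < bestf) { best <- a; bestf <- f }
        }
      }
      if (!is.na(best)) A <- c(A, best)
    }
  }
  if (length(fine$modes)) {
    fmax <- max(x[match(fine$modes, cls)])
    M <- M[x[match(M, cls)] > 0.01 * fmax]
  }
  list(modes = sort(M), antimodes = sort(A))
}

# Independent evaluation of the penalized distance: recompute robust
# critical points with the oracle above and apply the distance formula term
# by term on aligned CDFs.
oracle_dissimilarity <- function(orig_counts, sub_counts, classes,
                                 delta = 1, theta = 0.9, epsilon = 0,
                                 c1 = 10, c2 = 2, c3 = 1) {
  Fo <- cumsum(orig_counts) / sum(orig_counts)
  Go <- cumsum(sub_counts) / sum(sub_counts)
  l1 <- 0
  for (j in seq_along(classes)) l1 <- l1 + abs(Fo[j] - Go[j])
  co <- oracle_robust_cp(orig_counts, classes, delta)
  cs <- oracle_robust_cp(sub_counts, classes, delta)
  V <- sort(c(co$modes, co$antimodes))
  v <- sort(c(cs$modes, cs$antimodes))
  if (length(cs$modes) != length(co$modes) ||
      length(cs$antimodes) != length(co$antimodes))
    return(l1 + c1)
  pen2 <- 0
  for (i in seq_along(V)) pen2 <- pen2 + max(0, abs(v[i] - V[i]) - epsilon)
  pen3 <- 0
  if (length(V) >= 2) {
    for (i in 2:length(V)) {
      den <- abs(orig_counts[which(classes == V[i])] -
                   orig_counts[which(classes == V[i - 1])])
      if (den == 0) next
      num <- abs(sub_counts[which(classes == v[i])] -
                   sub_counts[which(classes == v[i - 1])])
      pen3 <- pen3 + max(0, theta - num / den)
    }
  }
  l1 + c2 * pen2 + c3 * pen3
}

# Random dense LFD for property tests (uses the caller's RNG stream).
random_lfd <- function(max_classes = 30, max_count = 20, min_classes = 3) {
  k <- sample(min_classes:max_classes, 1)
  start <- sample(1:60, 1)
  counts <- sample(0:max_count, k, replace = TRUE)
  if (all(counts == 0)) counts[sample(k, 1)] <- sample(1:max_count, 1)
  # ensure nonzero ends so the stored grid equals the support
  if (counts[1] == 0) counts[1] <- sample(1:max_count, 1)
  if (counts[k] == 0) counts[k] <- sample(1:max_count, 1)
  lfd(counts, classes = start + seq_len(k) - 1L)
}
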