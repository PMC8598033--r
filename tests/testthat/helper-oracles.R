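# Independent oracles used to freeze expected values. Each is a direct,
# unoptimized computation (double loops, exhaustive enumeration) kept
# deliberately separate from the package's implementation paths.

# Zernike moment magnitude by explicit per-pixel double sum
oracle_zernike <- function(mask, n, m) {
  idx <- which(mask > 0, arr.ind = TRUE)
  cen <- colMeans(idx)
  rmax <- max(sqrt((idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2))
  if (rmax == 0) rmax <- 1
  acc <- 0 + 0i
  for (r in seq_len(nrow(idx))) {
    dy <- idx[r, 1] - cen[1]; dx <- idx[r, 2] - cen[2]
    rho <- sqrt(dx^2 + dy^2) / rmax
    if (rho > 1) next
    theta <- atan2(dy, dx)
    Rnm <- 0
    for (s in 0:((n - m) / 2)) {
      Rnm <- Rnm + (-1)^s * factorial(n - s) /
        (factorial(s) * factorial((n + m) / 2 - s) *
           factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
    }
    acc <- acc + Rnm * exp(-1i * m * theta)
  }
  unname(Mod((n + 1) / pi * acc / rmax^2))
}

# symmetric normalized GLCM by explicit pair enumeration
oracle_glcm <- function(q, dr, dc, levels) {
  C <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + dr; j2 <- j + dc
    if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
    a <- q[i, j]; b <- q[i2, j2]
    if (is.na(a) || is.na(b)) next
    C[a, b] <- C[a, b] + 1
  }
  P <- C + t(C)
  if (sum(P) < 4) return(matrix(0, levels, levels))  # < 2 directed pairs
  P / sum(P)
}

# exhaustive best weighted stump over every (feature, midpoint, polarity)
oracle_stump <- function(X, y, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2L) next
    thrs <- (u[-length(u)] + u[-1]) / 2
    for (thr in thrs) for (pol in c(1L, -1L)) {
      pred <- if (pol > 0) as.integer(X[, j] > thr) else as.integer(X[, j] <= thr)
      err <- sum(w[pred != y])
      if (err < best$err - 1e-15) {
        best <- list(err = err, feature = j, threshold = thr, polarity = pol)
      }
    }
  }
  best
}

# exhaustive minimum-WCSS partition of n points into k non-empty clusters
oracle_best_wcss <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 10)
  best <- Inf
  assign_next <- function(asg, i) {
    if (i > n) {
      if (length(unique(asg)) != k) return(invisible())
      w <- 0
      for (cl in unique(asg)) {
        pts <- X[asg == cl, , drop = FALSE]
        cen <- colMeans(pts)
        w <- w + sum(sweep(pts, 2, cen)^2)
      }
      if (w < best) best <<- w
      return(invisible())
    }
    top <- min(max(asg[seq_len(i - 1)], 0) + 1L, k)
    for (cl in seq_len(top)) {
      asg[i] <- cl
      assign_next(asg, i + 1L)
    }
  }
  assign_next(integer(n), 1L)
  best
}

# homogeneity from raw counts, written directly from the entropy defs
oracle_homogeneity <- function(truth, clusters) {
  N <- length(truth)
  ea <- 0
  for (cl in unique(truth)) {
    p <- sum(truth == cl) / N
    ea <- ea - p * log(p)
  }
  if (ea == 0) return(1)
  eac <- 0
  for (cl in unique(truth)) for (k in unique(clusters)) {
    nmk <- sum(truth == cl & clusters == k)
    ck <- sum(clusters == k)
    if (nmk > 0) eac <- eac - (nmk / N) * log(nmk / ck)
  }
  1 - eac / ea
}

# rasterized disk mask: pixel centres within radius r of the centre
disk_mask <- function(r, pad = 3L) {
  n <- 2L * (ceiling(r) + pad) + 1L
  c0 <- (n + 1) / 2
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if ((i - c0)^2 + (j - c0)^2 <= r^2) m[i, j] <- 1L
  }
  m
}

# deterministic pseudo-random blob mask (star-convex around the centre)
blob_mask <- function(seed, size = 31L) {
  set.seed(seed)
  amps <- runif(4, 0, 0.25)
  phases <- runif(4, 0, 2 * pi)
  r0 <- size / 4
  c0 <- (size + 1) / 2
  m <- matrix(0L, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    th <- atan2(i - c0, j - c0)
    r <- r0 * (1 + sum(amps * cos((2:5) * th + phases)))
    if (sqrt((i - c0)^2 + (j - c0)^2) <= r) m[i, j] <- 1L
  }
  m
}
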