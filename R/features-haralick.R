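# Haralick texture statistics of the in-mask gray-level co-occurrence
# matrix. Intensities inside the mask are quantized to `levels` equal-width
# bins over the mask's own min-max range; for each (distance, angle) the
# GLCM counts pixel pairs both inside the mask, is symmetrized and
# normalized, and the 13 classical statistics are computed (natural
# logarithms; correlation defined as 0 when the marginal variance is 0).
# Offsets with fewer than 2 in-mask pairs yield 13 zeros.

quantize_mask <- function(crop, mask, levels) {
  v <- as.numeric(crop)[mask > 0]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(crop), ncol(crop))
  if (diff(rng) == 0) {
    q[mask > 0] <- 1L
  } else {
    q[mask > 0] <- pmin(as.integer(floor((as.numeric(crop)[mask > 0] - rng[1]) /
                                           diff(rng) * levels)) + 1L, levels)
  }
  q
}

glcm <- function(q, dr, dc, levels) {
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r0) == 0L || length(c0) == 0L) {
    return(matrix(0, levels, levels))
  }
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(matrix(0, levels, levels))
  C <- matrix(0, levels, levels)
  tab <- table(factor(a[ok], levels = seq_len(levels)),
               factor(b[ok], levels = seq_len(levels)))
  C <- matrix(as.numeric(tab), levels, levels)
  P <- C + t(C)
  P / sum(P)
}

haralick_stats <- function(P) {
  zero <- stats::setNames(numeric(13), c(
    "asm", "contrast", "correlation", "variance", "idm", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "diff_variance",
    "diff_entropy", "imc1", "imc2"))
  s <- sum(P)
  if (s == 0) return(zero)
  N <- nrow(P)
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  px <- rowSums(P)  # == colSums by symmetry
  mu <- sum(seq_len(N) * px)
  sig2 <- sum((seq_len(N) - mu)^2 * px)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0
  variance <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  # p_{x+y}(k), k = 2..2N; p_{x-y}(k), k = 0..N-1
  psum <- vapply(2:(2 * N), function(k) sum(P[(i + j) == k]), 0)
  pdiff <- vapply(0:(N - 1), function(k) sum(P[abs(i - j) == k]), 0)
  ks <- 2:(2 * N); kd <- 0:(N - 1)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(P))
  mud <- sum(kd * pdiff)
  diff_variance <- sum((kd - mud)^2 * pdiff)
  diff_entropy <- -sum(xlogx(pdiff))
  pxy <- px %o% px
  hxy1 <- -sum(ifelse(pxy > 0, P * log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  hx <- -sum(xlogx(px))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2)
}

# (dr, dc) offsets for the four standard angles at distance d
haralick_offsets <- function(d) {
  list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L), `135` = c(-d, -d))
}

#' Haralick texture features of a crop restricted to a mask
#'
#' @param crop grayscale matrix.
#' @param mask binary matrix of the same dimensions.
#' @param levels number of quantization levels, default 8.
#' @param distances pixel offsets, default `c(1, 2)`.
#' @return named numeric vector of 104 values (13 statistics x 2 distances
#'   x 4 angles) in manifest order `har_d{d}_a{angle}_{stat}`.
#' @export
haralick_features <- function(crop, mask, levels = 8L, distances = c(1L, 2L)) {
  stopifnot(all(dim(crop) == dim(mask)))
  if (sum(mask > 0) == 0L) stop("haralick_features: empty mask")
  q <- quantize_mask(crop, mask, levels)
  out <- numeric(0)
  for (d in distances) {
    offs <- haralick_offsets(as.integer(d))
    for (ang in names(offs)) {
      P <- glcm(q, offs[[ang]][1], offs[[ang]][2], levels)
      st <- haralick_stats(P)
      names(st) <- sprintf("har_d%d_a%s_%s", d, ang, names(st))
      out <- c(out, st)
    }
  }
  out
}
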