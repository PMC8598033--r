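# Zernike moment magnitudes of a binary mask over the unit disk.
# The mask is mapped to the unit disk centred at its centroid with radius
# equal to the maximum centroid-to-pixel distance, so the whole object
# lies inside the disk; pixels outside it are excluded. The complex
# moment uses the standard (n+1)/pi normalization; magnitudes |Z_nm| are
# rotation-invariant shape descriptors.

zernike_radial <- function(n, m, rho) {
  out <- numeric(length(rho))
  for (s in 0:((n - m) / 2)) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

#' Zernike moment magnitudes of a binary mask
#'
#' @param mask binary matrix (non-empty).
#' @return named numeric vector of the 30 manifest magnitudes
#'   `zernike_n{n}_m{m}`, n = 0..9, m >= 0, n - m even.
#' @export
zernike_features <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("zernike_features: empty mask")
  cen <- colMeans(idx)
  dy <- idx[, 1] - cen[1]
  dx <- idx[, 2] - cen[2]
  rmax <- max(sqrt(dx^2 + dy^2))
  if (rmax == 0) rmax <- 1  # single-pixel mask
  rho <- sqrt(dx^2 + dy^2) / rmax
  keep <- rho <= 1
  rho <- rho[keep]
  theta <- atan2(dy[keep], dx[keep])
  darea <- 1 / rmax^2  # pixel area in unit-disk coordinates
  ord <- zernike_orders()
  vals <- numeric(nrow(ord))
  for (i in seq_len(nrow(ord))) {
    n <- ord$n[i]; m <- ord$m[i]
    R <- zernike_radial(n, m, rho)
    z <- (n + 1) / pi * sum(R * exp(-1i * m * theta)) * darea
    vals[i] <- Mod(z)
  }
  stats::setNames(vals, sprintf("zernike_n%d_m%d", ord$n, ord$m))
}
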