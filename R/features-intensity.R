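#' Intensity features of a crop restricted to a mask
#'
#' Nine summaries of the in-mask pixel intensities: mean, median, SD, MAD,
#' min, max, integrated intensity (mean x area in pixels), mass
#' displacement (distance in pixels between the intensity-weighted and
#' binary centroids), and the edge-to-interior mean ratio (boundary pixels
#' vs eroded interior; 1 when the interior is empty).
#'
#' @param crop grayscale matrix.
#' @param mask binary matrix, same dimensions, non-empty.
#' @return named numeric vector of the 9 manifest intensity features.
#' @export
intensity_features <- function(crop, mask) {
  stopifnot(all(dim(crop) == dim(mask)))
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("intensity_features: empty mask")
  v <- as.numeric(crop)[mask > 0]
  cen_bin <- colMeans(idx)
  w <- v - min(v)
  cen_int <- if (sum(w) > 0) {
    c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  } else cen_bin
  md <- sqrt(sum((cen_int - cen_bin)^2))
  # boundary = mask pixels with a 4-neighbour outside the mask
  pad <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1L
  core <- pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  up <- pad[1:nrow(mask), 2:(ncol(mask) + 1L)]
  dn <- pad[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)]
  lf <- pad[2:(nrow(mask) + 1L), 1:ncol(mask)]
  rt <- pad[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
  edge <- core == 1L & (up + dn + lf + rt) < 4L
  interior <- core == 1L & !edge
  ratio <- if (any(interior)) {
    mi <- mean(as.numeric(crop)[interior])
    if (mi == 0) 1 else mean(as.numeric(crop)[edge]) / mi
  } else 1
  c(int_mean = mean(v), int_median = stats::median(v),
    int_sd = if (length(v) > 1L) stats::sd(v) else 0,
    int_mad = stats::mad(v), int_min = min(v), int_max = max(v),
    int_integrated = mean(v) * length(v),
    int_mass_displacement = md, int_edge_interior_ratio = ratio)
}
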