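# 26 shape descriptors from a binary single-component mask.
# Conventions: pixel centres at integer coordinates; lengths scaled to um
# by pixel_size; perimeter = Euclidean length of the ordered boundary
# chain through boundary-pixel centres; convex hull taken over boundary
# pixel centres so solidity <= 1 by construction.

# ordered boundary chain, 1-based (row, col) pixel-centre coordinates
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask))
  if (length(oc) == 0L) stop("empty mask has no contour")
  pts <- oc[[1]] + 1  # 0-based (dim1, dim2) -> 1-based (row, col)
  colnames(pts) <- c("r", "c")
  pts
}

chain_length <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt((pts[j, 1] - pts[, 1])^2 + (pts[j, 2] - pts[, 2])^2))
}

# perimeter of an 8-connected boundary chain with the Vossepoel-Smeulders
# step weights (0.948 axial, 1.340 diagonal), the standard correction for
# the overestimation of digital-circle perimeters by raw chain length
perimeter_chain <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  step2 <- (pts[j, 1] - pts[, 1])^2 + (pts[j, 2] - pts[, 2])^2
  diag <- step2 > 1.5
  sum(ifelse(diag, 1.340, 0.948) * sqrt(step2) / ifelse(diag, sqrt(2), 1))
}

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- length(x); j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# signed distance of points to the convex hull boundary (>= 0 inside)
hull_depths <- function(pts, hull) {
  nh <- nrow(hull)
  depth <- rep(Inf, nrow(pts))
  for (e in seq_len(nh)) {
    a <- hull[e, ]; b <- hull[if (e == nh) 1L else e + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    depth <- pmin(depth, sqrt(dx^2 + dy^2))
  }
  depth
}

count_holes <- function(mask) {
  pad <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  lab <- EBImage::bwlabel(EBImage::Image(1L - pad))
  labs <- EBImage::imageData(lab)
  border <- unique(c(labs[1, ], labs[nrow(labs), ], labs[, 1], labs[, ncol(labs)]))
  length(setdiff(unique(as.integer(labs)), c(0L, border)))
}

#' Shape features of a binary mask
#'
#' @param mask binary matrix with exactly one connected component.
#' @param pixel_size um per pixel (default 1: features in pixel units).
#' @return named numeric vector of the 26 manifest shape features.
#' @export
shape_features <- function(mask, pixel_size = 1) {
  px <- pixel_size
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("shape_features: empty mask")
  n <- nrow(idx)
  area <- n * px^2
  cen <- colMeans(idx)  # (row, col)
  pts <- mask_contour(mask)
  perim <- perimeter_chain(pts) * px
  # convex hull over boundary points (chull works in (x, y) = (col, row))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hull <- pts[h, , drop = FALSE]
  convex_perim <- chain_length(hull) * px
  # convex area by pixel count (centres inside or on the hull polygon),
  # so solidity = area / convex_area never exceeds 1
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  grid <- as.matrix(expand.grid(r = rr[1]:rr[2], c = cc[1]:cc[2]))
  convex_area_px <- max(sum(point_in_polygon(grid, hull)), n) * px^2
  solidity <- area / convex_area_px
  bbox_h <- diff(range(idx[, 1])) + 1L
  bbox_w <- diff(range(idx[, 2])) + 1L
  extent <- n / (bbox_h * bbox_w)
  # second central moments of the pixel distribution
  dr <- idx[, 1] - cen[1]; dc <- idx[, 2] - cen[2]
  mu20 <- mean(dc^2) + 1 / 12; mu02 <- mean(dr^2) + 1 / 12  # pixel-square term
  mu11 <- mean(dr * dc)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(pmax(l1, 0)) * px
  minor <- 4 * sqrt(pmax(l2, 0)) * px
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  aspect <- if (minor > 0) major / minor else 1
  orientation <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  form_factor <- if (perim > 0) 4 * pi * area / perim^2 else 0
  compactness <- if (area > 0 && perim > 0) perim^2 / (4 * pi * area) else 0
  eqd <- 2 * sqrt(area / pi)
  euler <- 1 - count_holes(mask)
  radii <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2) * px
  feret <- feret_diameters(hull) * px
  roughness <- if (convex_perim > 0) perim / convex_perim else 1
  bbox_cen <- c(mean(range(idx[, 1])), mean(range(idx[, 2])))
  cen_off <- sqrt(sum((cen - bbox_cen)^2)) * px
  depth <- hull_depths(pts, hull)
  conc <- concavity_runs(depth, min_depth = 0.5)
  c(area = area, perimeter = perim, convex_area = convex_area_px,
    solidity = solidity, extent = extent, eccentricity = ecc,
    major_axis_length = major, minor_axis_length = minor,
    aspect_ratio = aspect, orientation = orientation,
    form_factor = form_factor, compactness = compactness,
    equivalent_diameter = eqd, euler_number = euler,
    max_radius = max(radii), min_radius = min(radii),
    mean_radius = mean(radii), median_radius = stats::median(radii),
    feret_max = unname(feret["max"]), feret_min = unname(feret["min"]),
    boundary_roughness = roughness, centroid_offset = cen_off,
    n_concavities = unname(conc["n"]),
    mean_concavity_depth = unname(conc["depth"]) * px,
    radial_variance = stats::var(radii),
    mass_displacement_shape = 0)
}

# ray-casting point-in-polygon (points on edges count as inside)
point_in_polygon <- function(pts, poly) {
  x <- pts[, 2]; y <- pts[, 1]
  px_ <- poly[, 2]; py_ <- poly[, 1]
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cond <- ((py_[i] > y) != (py_[j] > y))
    xi <- px_[j] + (y - py_[j]) * (px_[i] - px_[j]) /
      ifelse(py_[i] == py_[j], 1, (py_[i] - py_[j]))
    inside <- xor(inside, cond & (x < xi))
    j <- i
  }
  # also accept points within half a pixel of the hull boundary
  inside | hull_depths(pts, poly) <= 0.5
}

feret_diameters <- function(hull) {
  nh <- nrow(hull)
  if (nh == 1L) return(c(max = 0, min = 0))
  d2 <- as.matrix(stats::dist(hull))
  fmax <- max(d2)
  # rotating-calipers width: min over hull edges of the max point-line distance
  fmin <- Inf
  for (e in seq_len(nh)) {
    a <- hull[e, ]; b <- hull[if (e == nh) 1L else e + 1L, ]
    ab <- b - a; len <- sqrt(sum(ab^2))
    if (len == 0) next
    w <- max(abs((hull[, 1] - a[1]) * ab[2] - (hull[, 2] - a[2]) * ab[1]) / len)
    fmin <- min(fmin, w)
  }
  if (!is.finite(fmin)) fmin <- 0
  c(max = fmax, min = fmin)
}

# circular runs of boundary points deeper than min_depth below the hull
concavity_runs <- function(depth, min_depth = 0.5) {
  deep <- depth > min_depth
  if (!any(deep)) return(c(n = 0, depth = 0))
  n <- length(deep)
  # rotate so the run boundary is not split across the wrap-around
  if (all(deep)) return(c(n = 1, depth = max(depth)))
  start <- which(!deep)[1]
  deep <- deep[c(start:n, seq_len(start - 1L))]
  dd <- depth[c(start:n, seq_len(start - 1L))]
  r <- rle(deep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  depths <- vapply(runs, function(k) max(dd[starts[k]:ends[k]]), 0)
  c(n = length(runs), depth = mean(depths))
}
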