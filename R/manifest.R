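#' The fixed 169-entry morphology feature manifest
#'
#' Every feature table produced or consumed by this package carries exactly
#' these 169 numeric columns, in this order: 26 shape descriptors, 30 Zernike
#' moment magnitudes (order n = 0..9, repetition m >= 0 with n - m even),
#' 104 Haralick texture statistics (13 statistics x 2 distances x 4 angles)
#' and 9 intensity summaries. The manifest is a fixed reconstruction of a
#' CellProfiler-style export: the feature families and the total count are
#' standard, the exact member list is versioned here.
#'
#' @return A data.frame with columns `name` (unique feature name), `group`
#'   (one of `"shape"`, `"zernike"`, `"haralick"`, `"intensity"`) and
#'   `index` (1..169, the fixed column order).
#' @examples
#' m <- feature_manifest()
#' nrow(m)            # 169
#' table(m$group)
#' @export
feature_manifest <- function() {
  shape <- c(
    "area", "perimeter", "convex_area", "solidity", "extent", "eccentricity",
    "major_axis_length", "minor_axis_length", "aspect_ratio", "orientation",
    "form_factor", "compactness", "equivalent_diameter", "euler_number",
    "max_radius", "min_radius", "mean_radius", "median_radius",
    "feret_max", "feret_min", "boundary_roughness", "centroid_offset",
    "n_concavities", "mean_concavity_depth", "radial_variance",
    "mass_displacement_shape"
  )
  zp <- zernike_orders()
  zern <- sprintf("zernike_n%d_m%d", zp$n, zp$m)
  stats13 <- c(
    "asm", "contrast", "correlation", "variance", "idm", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "diff_variance",
    "diff_entropy", "imc1", "imc2"
  )
  har <- as.vector(outer(
    stats13,
    as.vector(outer(c(0, 45, 90, 135), c(1, 2),
                    function(a, d) sprintf("d%d_a%d", d, a))),
    function(s, da) sprintf("har_%s_%s", da, s)
  ))
  # outer() above builds stat-major order; rebuild explicitly distance-major,
  # angle, then statistic so the order is unambiguous
  har <- character(0)
  for (d in c(1L, 2L)) for (a in c(0L, 45L, 90L, 135L)) {
    har <- c(har, sprintf("har_d%d_a%d_%s", d, a, stats13))
  }
  intens <- c(
    "int_mean", "int_median", "int_sd", "int_mad", "int_min", "int_max",
    "int_integrated", "int_mass_displacement", "int_edge_interior_ratio"
  )
  nm <- c(shape, zern, har, intens)
  grp <- c(
    rep("shape", length(shape)), rep("zernike", length(zern)),
    rep("haralick", length(har)), rep("intensity", length(intens))
  )
  stopifnot(length(nm) == 169L, !anyDuplicated(nm))
  data.frame(name = nm, group = grp, index = seq_along(nm),
             stringsAsFactors = FALSE)
}

#' Zernike (n, m) order pairs used by the manifest
#'
#' All pairs with n = 0..9, m >= 0, n - m even: 30 pairs.
#' @return data.frame with integer columns `n`, `m`.
#' @export
zernike_orders <- function() {
  out <- do.call(rbind, lapply(0:9, function(n) {
    m <- seq(n %% 2, n, by = 2)
    data.frame(n = n, m = m)
  }))
  stopifnot(nrow(out) == 30L)
  out
}

#' Validate a feature table against the manifest schema
#'
#' Checks that `x` contains `cell_id`, `time_min` and all 169 manifest
#' columns (extra metadata columns such as `label` are permitted).
#'
#' @param x data.frame to validate.
#' @return `x` invisibly; stops with a message naming missing/unknown
#'   manifest columns otherwise.
#' @export
validate_feature_table <- function(x) {
  stopifnot(is.data.frame(x))
  man <- feature_manifest()$name
  missing <- setdiff(c("cell_id", "time_min", man), names(x))
  if (length(missing) > 0L) {
    stop("feature table is missing required column(s): ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (+%d more)", length(missing) - 10L))
  }
  if (any(x$time_min < 0)) stop("time_min must be non-negative")
  bad <- man[vapply(x[man], function(col) anyNA(col), logical(1))]
  if (length(bad) > 0L) {
    stop("feature table has missing values in: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(x)
}
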