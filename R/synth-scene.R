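# Scene assembly: ground truth table, per-well cell states, frame rendering.

#' Draw the per-well ground truth for a scene
#'
#' Assigns each well an occupancy (empty / single / multi), a phenotype
#' class and sub-phenotype drawn from `mix`, and a viability flag. The
#' table is the evaluation oracle for segmentation and filtering.
#'
#' @param plan a [scene_plan()].
#' @param phenotypes named list of [phenotype_spec()] objects.
#' @param mix named numeric vector of class probabilities over
#'   `names(phenotypes)`; default uniform.
#' @param seed integer; default `plan$seed`.
#' @return data.frame with one row per well: `well_id` (row-major, 1-based),
#'   `row`, `col`, `occupancy`, `class_label`, `subphenotype_id`, `alive`.
#'   `class_label`/`subphenotype_id` are `NA` iff the well is empty.
#' @export
make_ground_truth <- function(plan, phenotypes, mix = NULL, seed = plan$seed) {
  stopifnot(inherits(plan, "scene_plan"), length(phenotypes) >= 1L)
  if (is.null(names(phenotypes)) || any(names(phenotypes) == "")) {
    names(phenotypes) <- vapply(phenotypes, `[[`, "", "name")
  }
  if (is.null(mix)) mix <- stats::setNames(rep(1, length(phenotypes)),
                                           names(phenotypes))
  mix <- mix / sum(mix)
  n <- plan$grid_rows * plan$grid_cols
  with_seed(substream_seed(seed, "truth"), {
    occ <- sample(c("empty", "single", "multi"), n, replace = TRUE,
                  prob = c(plan$p_empty, plan$p_single, plan$p_multi))
    cls <- sample(names(phenotypes), n, replace = TRUE, prob = mix)
    sub <- vapply(cls, function(cl)
      sample.int(length(phenotypes[[cl]]$subphenotypes), 1L), 1L)
    alive <- stats::runif(n) >= plan$dead_fraction
    cls[occ == "empty"] <- NA_character_
    sub[occ == "empty"] <- NA_integer_
    alive[occ == "empty"] <- NA
    data.frame(
      well_id = seq_len(n),
      row = rep(seq_len(plan$grid_rows), each = plan$grid_cols),
      col = rep(seq_len(plan$grid_cols), times = plan$grid_rows),
      occupancy = occ, class_label = cls, subphenotype_id = sub,
      alive = alive, stringsAsFactors = FALSE
    )
  })
}

# one cell-state list per well: list of (state, dx, dy) for each cell present
build_scene_states <- function(plan, phenotypes, truth, seed = plan$seed) {
  if (is.null(names(phenotypes)) || any(names(phenotypes) == "")) {
    names(phenotypes) <- vapply(phenotypes, `[[`, "", "name")
  }
  lapply(seq_len(nrow(truth)), function(w) {
    occ <- truth$occupancy[w]
    if (occ == "empty") return(list())
    ncell <- if (occ == "multi") 2L else 1L
    spec <- apply_subphenotype(phenotypes[[truth$class_label[w]]],
                               truth$subphenotype_id[w])
    lapply(seq_len(ncell), function(i) {
      st <- cell_shape_state(spec, frames = plan$frames,
                             frame_interval_min = plan$frame_interval_min,
                             seed = substream_seed(seed, "cell", w * 8L + i))
      off <- if (ncell == 1L) c(0, 0) else {
        d <- plan$well_pitch_um / 6
        if (i == 1L) c(-d, -d / 2) else c(d, d / 2)
      }
      list(state = st, dx = off[1], dy = off[2])
    })
  })
}

well_center_um <- function(plan, row, col) {
  c(x = (col - 0.5) * plan$well_pitch_um,
    y = (row - 0.5) * plan$well_pitch_um)
}

# pixel coordinates (row-index i downwards = y, col-index j = x)
scene_dims_px <- function(plan) {
  c(rows = as.integer(round(plan$grid_rows * plan$well_pitch_um /
                              plan$pixel_size_um)),
    cols = as.integer(round(plan$grid_cols * plan$well_pitch_um /
                              plan$pixel_size_um)))
}

# draw the triangular well outlines into a signal matrix (adds `level`)
draw_well_outlines <- function(sig, plan, level = 60) {
  px <- plan$pixel_size_um
  R <- plan$well_side_um / sqrt(3)  # circumradius of equilateral triangle
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  for (r in seq_len(plan$grid_rows)) for (cc in seq_len(plan$grid_cols)) {
    cen <- well_center_um(plan, r, cc)
    vx <- cen["x"] + R * cos(ang); vy <- cen["y"] + R * sin(ang)
    for (e in 1:3) {
      e2 <- if (e == 3L) 1L else e + 1L
      len <- sqrt((vx[e2] - vx[e])^2 + (vy[e2] - vy[e])^2)
      s <- seq(0, 1, length.out = max(2L, ceiling(len / px * 2)))
      xs <- vx[e] + s * (vx[e2] - vx[e]); ys <- vy[e] + s * (vy[e2] - vy[e])
      i <- pmax(1L, pmin(nrow(sig), as.integer(ceiling(ys / px))))
      j <- pmax(1L, pmin(ncol(sig), as.integer(ceiling(xs / px))))
      sig[cbind(i, j)] <- sig[cbind(i, j)] * 0 + level + attr(sig, "bg")
    }
  }
  sig
}

# rasterize one cell into the signal matrix: adds intensity where the pixel
# centre lies inside the star-convex outline (exact radial test)
add_cell_signal <- function(sig, plan, cx, cy, state, t, intensity) {
  px <- plan$pixel_size_um
  rmax <- state$spec$base_radius_um * (1.8 + state$spec$protrusion_amplitude)
  i0 <- max(1L, floor((cy - rmax) / px)); i1 <- min(nrow(sig), ceiling((cy + rmax) / px))
  j0 <- max(1L, floor((cx - rmax) / px)); j1 <- min(ncol(sig), ceiling((cx + rmax) / px))
  if (i0 > i1 || j0 > j1) return(sig)
  ii <- i0:i1; jj <- j0:j1
  ycoord <- (ii - 0.5) * px - cy
  xcoord <- (jj - 0.5) * px - cx
  Y <- matrix(ycoord, nrow = length(ii), ncol = length(jj))
  X <- matrix(xcoord, nrow = length(ii), ncol = length(jj), byrow = TRUE)
  rho <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)
  rb <- cell_radius(state, as.vector(theta), t)
  inside <- as.vector(rho) <= rb
  block <- sig[ii, jj, drop = FALSE]
  block[inside] <- block[inside] + intensity
  sig[ii, jj] <- block
  sig
}

#' Render one frame of a synthetic scene
#'
#' Builds the noiseless signal (constant background + triangular well
#' outlines + filled cell silhouettes at their phenotype's mean intensity),
#' then applies Poisson shot noise and Gaussian read noise unless
#' `plan$noise_gaussian_sd == 0`. In the `"main"` fluorescence channel all
#' cells are rendered (dead cells as static, non-rotating silhouettes); in
#' the `"viability"` channel only dead cells appear, emulating an
#' end-of-run propidium-iodide stain.
#'
#' @param plan a [scene_plan()].
#' @param truth ground truth from [make_ground_truth()].
#' @param states per-well cell states from `build_scene_states()`.
#' @param t time in minutes.
#' @param channel `"main"` or `"viability"`.
#' @param seed noise seed for this frame.
#' @return integer matrix (16-bit grayscale range, 0..65535).
#' @export
render_frame <- function(plan, truth, states, t, channel = c("main", "viability"),
                         seed = plan$seed) {
  channel <- match.arg(channel)
  dims <- scene_dims_px(plan)
  if (prod(as.double(dims)) > plan$max_pixels) {
    stop(sprintf("frame would be %.0f pixels (> max_pixels = %.0f)",
                 prod(as.double(dims)), plan$max_pixels))
  }
  sig <- matrix(0, dims["rows"], dims["cols"])
  attr(sig, "bg") <- 0
  if (channel == "main") sig <- draw_well_outlines(sig, plan)
  sig <- sig + plan$background_level
  for (w in seq_len(nrow(truth))) {
    if (truth$occupancy[w] == "empty") next
    alive <- isTRUE(truth$alive[w])
    if (channel == "main") render_this <- TRUE
    else render_this <- !alive
    if (!render_this) next
    cen <- well_center_um(plan, truth$row[w], truth$col[w])
    t_eff <- if (alive) t else 0  # dead cells do not rotate or deform
    for (cell in states[[w]]) {
      sig <- add_cell_signal(sig, plan, cen["x"] + cell$dx, cen["y"] + cell$dy,
                             cell$state, t_eff, cell$state$spec$intensity_mean)
    }
  }
  if (plan$noise_gaussian_sd > 0) {
    img <- with_seed(substream_seed(seed, paste0("noise_", channel),
                                    as.integer(round(t * 1000))), {
      stats::rpois(length(sig), lambda = as.vector(sig)) +
        stats::rnorm(length(sig), 0, plan$noise_gaussian_sd)
    })
    sig <- matrix(img, nrow(sig), ncol(sig))
  }
  m <- matrix(as.integer(pmin(pmax(round(sig), 0), 65535)),
              nrow(sig), ncol(sig))
  m
}

#' Simulate a full microwell time-lapse
#'
#' Renders `plan$frames` main-channel frames at `plan$frame_interval_min`
#' spacing (timestamps 0, 1, ... minutes by default), one end-of-run
#' viability frame, and the ground-truth table. Fully reproducible from
#' the seed.
#'
#' @inheritParams make_ground_truth
#' @return list with elements `frames` (list of integer matrices),
#'   `times_min`, `viability` (integer matrix), `truth`, `states`, `plan`.
#' @export
simulate_timelapse <- function(plan, phenotypes, mix = NULL, seed = plan$seed) {
  truth <- make_ground_truth(plan, phenotypes, mix, seed = seed)
  states <- build_scene_states(plan, phenotypes, truth, seed = seed)
  times <- (seq_len(plan$frames) - 1L) * plan$frame_interval_min
  frames <- lapply(times, function(t)
    render_frame(plan, truth, states, t, "main", seed = seed))
  viability <- render_frame(plan, truth, states, max(times), "viability",
                            seed = seed)
  list(frames = frames, times_min = times, viability = viability,
       truth = truth, states = states, plan = plan)
}

#' Rasterize a cell's true outline into a well-local binary mask
#'
#' Evaluation helper: the ground-truth mask for the cell(s) in well `w`
#' at time `t`, on the same pixel grid as the rendered frame restricted to
#' the well's bounding box.
#'
#' @param scene result of [simulate_timelapse()].
#' @param w well id.
#' @param t time (minutes).
#' @param box bounding box as returned by [locate_wells()] (row of it).
#' @return binary matrix of the box's dimensions.
#' @export
truth_mask <- function(scene, w, t, box) {
  plan <- scene$plan
  px <- plan$pixel_size_um
  ii <- (box$y0 + 1L):box$y1; jj <- (box$x0 + 1L):box$x1
  mask <- matrix(0L, length(ii), length(jj))
  tr <- scene$truth[w, ]
  if (tr$occupancy == "empty") return(mask)
  cen <- well_center_um(plan, tr$row, tr$col)
  t_eff <- if (isTRUE(tr$alive)) t else 0
  for (cell in scene$states[[w]]) {
    cx <- cen["x"] + cell$dx; cy <- cen["y"] + cell$dy
    Y <- matrix((ii - 0.5) * px - cy, length(ii), length(jj))
    X <- matrix((jj - 0.5) * px - cx, length(ii), length(jj), byrow = TRUE)
    rho <- sqrt(X^2 + Y^2); theta <- atan2(Y, X)
    rb <- cell_radius(cell$state, as.vector(theta), t_eff)
    mask[as.vector(rho) <= rb] <- 1L
  }
  mask
}
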