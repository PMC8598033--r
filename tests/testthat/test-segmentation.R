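# Well cropping, delineation, occupancy classification, viability filtering.

seg_spec <- function() {
  phenotype_spec("cell", amp_mean = c(0.1, 0.05, 0, 0, 0), amp_sd = 0.02,
                 protrusion_rate = 0.1)
}

noiseless_plan <- function(...) {
  scene_plan(noise_gaussian_sd = 0, ...)
}

test_that("locate_wells tiles the grid and flags boxes beyond the image", {
  plan <- noiseless_plan(grid_rows = 10, grid_cols = 10, frames = 1, seed = 1)
  dims <- morphodyn:::scene_dims_px(plan)
  boxes <- locate_wells(dims, plan)
  expect_equal(nrow(boxes), 100)
  # boxes tile without overlap: total area equals image area
  expect_equal(sum((boxes$y1 - boxes$y0) * (boxes$x1 - boxes$x0)),
               prod(as.numeric(dims)))
  expect_error(locate_wells(dims, c(plan, list(origin_px = c(80L, 80L)))),
               "exceed")
})

test_that("every truth cell centroid falls inside its assigned box", {
  plan <- noiseless_plan(grid_rows = 4, grid_cols = 4, frames = 1,
                         p_empty = 0.2, p_single = 0.8, p_multi = 0,
                         dead_fraction = 0, seed = 8)
  sc <- simulate_timelapse(plan, list(cell = seg_spec()))
  boxes <- locate_wells(dim(sc$frames[[1]]), plan)
  px <- plan$pixel_size_um
  for (w in which(sc$truth$occupancy != "empty")) {
    cen <- morphodyn:::well_center_um(plan, sc$truth$row[w], sc$truth$col[w])
    b <- boxes[boxes$well_id == w, ]
    expect_true(cen["y"] / px > b$y0 && cen["y"] / px <= b$y1)
    expect_true(cen["x"] / px > b$x0 && cen["x"] / px <= b$x1)
  }
})

test_that("delineation recovers the true mask with IoU >= 0.95 when noiseless", {
  plan <- noiseless_plan(grid_rows = 2, grid_cols = 2, frames = 1,
                         p_empty = 0, p_single = 1, p_multi = 0,
                         dead_fraction = 0, seed = 3)
  sc <- simulate_timelapse(plan, list(cell = seg_spec()))
  boxes <- locate_wells(dim(sc$frames[[1]]), plan)
  for (w in 1:4) {
    b <- boxes[boxes$well_id == w, ]
    crop <- morphodyn:::crop_box(sc$frames[[1]], b)
    mask <- delineate_cell(crop)
    tm <- truth_mask(sc, w, 0, b)
    iou <- sum(mask & tm) / sum(mask | tm)
    expect_gte(iou, 0.95)
  }
})

test_that("mean IoU stays >= 0.8 at the default noise level", {
  plan <- scene_plan(grid_rows = 3, grid_cols = 3, frames = 2,
                     p_empty = 0, p_single = 1, p_multi = 0,
                     dead_fraction = 0, seed = 19)
  sc <- simulate_timelapse(plan, list(cell = seg_spec()))
  boxes <- locate_wells(dim(sc$frames[[1]]), plan)
  ious <- c()
  for (w in seq_len(9)) for (f in 1:2) {
    b <- boxes[boxes$well_id == w, ]
    mask <- delineate_cell(morphodyn:::crop_box(sc$frames[[f]], b))
    tm <- truth_mask(sc, w, sc$times_min[f], b)
    ious <- c(ious, sum(mask & tm) / sum(mask | tm))
  }
  expect_gte(mean(ious), 0.8)
})

test_that("masks are invariant to a constant intensity offset", {
  plan <- noiseless_plan(grid_rows = 1, grid_cols = 1, frames = 1,
                         p_empty = 0, p_single = 1, p_multi = 0,
                         dead_fraction = 0, seed = 4)
  sc <- simulate_timelapse(plan, list(cell = seg_spec()))
  crop <- sc$frames[[1]]
  expect_identical(delineate_cell(crop), delineate_cell(crop + 500))
})

test_that("pure background patches give empty masks and empty occupancy", {
  flat <- matrix(200L, 80, 80)
  expect_equal(sum(delineate_cell(flat)), 0)
  expect_identical(classify_occupancy(flat), "empty")
  set.seed(5)
  noisy <- matrix(as.integer(200 + rnorm(6400, 0, 15)), 80, 80)
  expect_identical(classify_occupancy(noisy), "empty")
})

test_that("two equal objects: one component kept, occupancy reports multi", {
  m <- matrix(0L, 60, 60)
  m[10:20, 10:20] <- 1000L
  m[40:50, 40:50] <- 1000L
  mask <- delineate_cell(m, sigma = 0)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  expect_equal(max(EBImage::imageData(lab)), 1)
  # tie on size: the component earliest in scan order is the one kept
  expect_true(mask[15, 15] == 1L && mask[45, 45] == 0L)
  expect_identical(classify_occupancy(m), "multi")
})

test_that("occupancy classification is exact on a noiseless scene", {
  plan <- noiseless_plan(grid_rows = 5, grid_cols = 5, frames = 1,
                         p_empty = 0.3, p_single = 0.5, p_multi = 0.2,
                         dead_fraction = 0, seed = 6)
  sc <- simulate_timelapse(plan, list(cell = seg_spec()))
  boxes <- locate_wells(dim(sc$frames[[1]]), plan)
  got <- vapply(seq_len(25), function(w)
    classify_occupancy(morphodyn:::crop_box(sc$frames[[1]],
                                            boxes[boxes$well_id == w, ])), "")
  expect_identical(unname(got), sc$truth$occupancy)
})

test_that("noiseless end-to-end retains exactly the single live cells", {
  plan <- noiseless_plan(grid_rows = 6, grid_cols = 6, frames = 3,
                         p_empty = 0.25, p_single = 0.6, p_multi = 0.15,
                         dead_fraction = 0.25, seed = 14)
  sc <- simulate_timelapse(plan, list(cell = seg_spec()))
  cells <- segment_timelapse(sc$frames, plan, sc$times_min)
  cells <- suppressMessages(filter_viability(cells, sc$viability, plan))
  got <- sort(vapply(cells, `[[`, 0, "cell_id"))
  want <- sort(sc$truth$well_id[sc$truth$occupancy == "single" &
                                  sc$truth$alive %in% TRUE])
  expect_identical(got, as.numeric(want))
  n_dead_single <- sum(sc$truth$occupancy == "single" & sc$truth$alive %in% FALSE)
  expect_equal(attr(cells, "n_dropped"), n_dead_single)
})

test_that("viability filter degenerate paths", {
  plan <- noiseless_plan(grid_rows = 3, grid_cols = 3, frames = 2,
                         p_empty = 0, p_single = 1, p_multi = 0,
                         dead_fraction = 0, seed = 7)
  sc <- simulate_timelapse(plan, list(cell = seg_spec()))
  cells <- segment_timelapse(sc$frames, plan, sc$times_min)
  # no dead cells: nothing dropped
  kept <- suppressMessages(filter_viability(cells, sc$viability, plan))
  expect_equal(attr(kept, "n_dropped"), 0L)
  expect_equal(length(kept), length(cells))
  # missing viability frame: pass-through with warning
  expect_warning(out <- suppressMessages(filter_viability(cells, NULL, plan)),
                 "no viability frame")
  expect_equal(length(out), length(cells))
  # all wells dead: empty output with explicit warning
  plan2 <- noiseless_plan(grid_rows = 3, grid_cols = 3, frames = 2,
                          p_empty = 0, p_single = 1, p_multi = 0,
                          dead_fraction = 1, seed = 9)
  sc2 <- simulate_timelapse(plan2, list(cell = seg_spec()))
  cells2 <- segment_timelapse(sc2$frames, plan2, sc2$times_min)
  expect_warning(
    out2 <- suppressMessages(filter_viability(cells2, sc2$viability, plan2)),
    "all cells failed")
  expect_equal(length(out2), 0L)
})
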