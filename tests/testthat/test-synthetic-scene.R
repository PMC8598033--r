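# Synthetic scene generator: shape model, rendering, occupancy, determinism.

circle_spec <- function() {
  phenotype_spec("circ", amp_mean = rep(0, 5), amp_sd = 0,
                 lobe_drift_rate = 0, protrusion_rate = 0)
}

test_that("zero-amplitude outline is a circle of the base radius", {
  spec <- circle_spec()
  st <- cell_shape_state(spec, frames = 10, seed = 4)
  for (t in c(0, 3.5, 9)) {
    poly <- simulate_cell_outline(spec, t, state = st)
    r <- sqrt(poly$x^2 + poly$y^2)
    expect_equal(r, rep(spec$base_radius_um, nrow(poly)), tolerance = 1e-12)
  }
})

test_that("polygon area of the zero-amplitude outline matches pi r^2 within 1%", {
  spec <- circle_spec()
  poly <- simulate_cell_outline(spec, 0, n_vertices = 256, seed = 1)
  expect_lt(abs(morphodyn:::polygon_area(poly) - pi * spec$base_radius_um^2) /
              (pi * spec$base_radius_um^2), 0.01)
})

test_that("with drift and protrusions disabled, the outline rotates rigidly", {
  # 0.1 Hz x 60 s = 6 full turns per minute: frames are identical; at
  # fractional times the outline equals frame 0 rotated by the same angle
  spec <- phenotype_spec("lobed", amp_mean = c(0.15, 0.08, 0, 0, 0),
                         amp_sd = 0, lobe_drift_rate = 0, protrusion_rate = 0)
  st <- cell_shape_state(spec, frames = 10, seed = 7)
  theta <- seq(0, 2 * pi, length.out = 129)[-129]
  r0 <- morphodyn:::cell_radius(st, theta, 0)
  for (n in c(1, 2, 5)) {
    expect_equal(morphodyn:::cell_radius(st, theta, n), r0, tolerance = 1e-9)
  }
  t_frac <- 0.25  # quarter minute = 1.5 turns = half turn net
  ang <- 2 * pi * spec$rotation_freq_hz * 60 * t_frac
  r_rot <- morphodyn:::cell_radius(st, theta + ang, t_frac)
  expect_equal(r_rot, r0, tolerance = 1e-9)
})

test_that("image sequence is periodic with period 1/(f*60) minutes", {
  spec <- phenotype_spec("slow", amp_mean = c(0, 0.2, 0, 0, 0), amp_sd = 0,
                         lobe_drift_rate = 0, protrusion_rate = 0,
                         rotation_freq_hz = 1 / 120)  # period 2 min
  plan <- scene_plan(grid_rows = 1, grid_cols = 1, frames = 5,
                     p_empty = 0, p_single = 1, p_multi = 0,
                     dead_fraction = 0, noise_gaussian_sd = 0, seed = 3)
  sc <- simulate_timelapse(plan, list(slow = spec))
  expect_identical(sc$frames[[1]], sc$frames[[3]])
  expect_identical(sc$frames[[2]], sc$frames[[4]])
  expect_false(identical(sc$frames[[1]], sc$frames[[2]]))
})

test_that("occupancy fractions follow the plan probabilities (chi-square)", {
  plan <- scene_plan(grid_rows = 100, grid_cols = 100, frames = 1,
                     p_empty = 0.25, p_single = 0.60, p_multi = 0.15, seed = 21)
  truth <- make_ground_truth(plan, list(c = circle_spec()))
  counts <- table(factor(truth$occupancy, c("empty", "single", "multi")))
  p <- stats::chisq.test(counts, p = c(0.25, 0.60, 0.15))$p.value
  expect_gt(p, 0.01)
  # >60% single occupancy, as in the loading protocol being emulated
  expect_gt(mean(truth$occupancy == "single"), 0.55)
})

test_that("noise-free all-empty scene renders background plus outlines only", {
  plan <- scene_plan(grid_rows = 2, grid_cols = 2, frames = 1,
                     p_empty = 1, p_single = 0, p_multi = 0,
                     noise_gaussian_sd = 0, seed = 5)
  truth <- make_ground_truth(plan, list(c = circle_spec()))
  states <- morphodyn:::build_scene_states(plan, list(c = circle_spec()), truth)
  img <- render_frame(plan, truth, states, 0)
  expect_setequal(unique(as.vector(img)),
                  c(plan$background_level, plan$background_level + 60))
})

test_that("rendered cell pixel count matches the outline area within 5%", {
  spec <- circle_spec()
  plan <- scene_plan(grid_rows = 1, grid_cols = 1, frames = 1,
                     p_empty = 0, p_single = 1, p_multi = 0,
                     dead_fraction = 0, noise_gaussian_sd = 0, seed = 2)
  sc <- simulate_timelapse(plan, list(circ = spec))
  npix <- sum(sc$frames[[1]] > plan$background_level + 60)
  poly <- simulate_cell_outline(spec, 0, state = sc$states[[1]][[1]]$state,
                                n_vertices = 512)
  expect_lt(abs(npix - morphodyn:::polygon_area(poly) / plan$pixel_size_um^2) /
              npix, 0.05)
})

test_that("time-lapse timestamps, determinism, and dead-cell counts", {
  plan <- scene_plan(grid_rows = 8, grid_cols = 8, frames = 4,
                     dead_fraction = 0.2, p_empty = 0.1, p_single = 0.9,
                     p_multi = 0, seed = 11)
  spec <- circle_spec()
  sc1 <- simulate_timelapse(plan, list(circ = spec))
  sc2 <- simulate_timelapse(plan, list(circ = spec))
  expect_identical(sc1$times_min, (0:3) * 1)
  expect_identical(sc1$frames, sc2$frames)        # same seed, same bytes
  expect_identical(sc1$viability, sc2$viability)
  occupied <- sc1$truth$occupancy != "empty"
  n_dead <- sum(!sc1$truth$alive[occupied])
  expect_gt(n_dead, 0)
  bt <- stats::binom.test(n_dead, sum(occupied), 0.2)$p.value
  expect_gt(bt, 0.001)
  sc3 <- simulate_timelapse(plan, list(circ = spec), seed = 12)
  expect_false(identical(sc1$frames, sc3$frames))  # different seed differs
})

test_that("feature table has the fixed 169 columns and planted structure", {
  ft <- simulate_feature_table(c(A = 6, B = 6), timepoints = 4, seed = 2)
  expect_identical(names(ft$features),
                   c("cell_id", "time_min", feature_manifest()$name))
  expect_equal(nrow(ft$features), 12 * 4)
  expect_identical(sort(unique(ft$labels$subphenotype_id)), 1:7)
  expect_error(simulate_feature_table(c(A = 0, B = 3), 4), "positive")
})

test_that("null effect size gives identical class-conditional distributions", {
  ft <- simulate_feature_table(c(A = 120, B = 120), timepoints = 1,
                               effect_size = 0, mixture = c(A = 1L, B = 1L),
                               seed = 9)
  man <- feature_manifest()$name
  a <- ft$features[ft$features$cell_id %in%
                     ft$labels$cell_id[ft$labels$class == "A"], man[1]]
  b <- ft$features[ft$features$cell_id %in%
                     ft$labels$cell_id[ft$labels$class == "B"], man[1]]
  expect_gt(stats::t.test(a, b)$p.value, 0.001)
  expect_gt(stats::ks.test(a, b)$p.value, 0.001)
})

test_that("generated column variance matches the configured unit variance", {
  ft <- simulate_feature_table(c(A = 1000, B = 1000), timepoints = 5,
                               mixture = c(A = 1L, B = 1L), seed = 13)
  # a column with no planted structure: marginal variance 1 within 10%
  v <- stats::var(ft$features$int_mean)
  expect_lt(abs(v - 1), 0.1)
})

test_that("feature generation is reproducible from the seed", {
  f1 <- simulate_feature_table(c(A = 5, B = 5), timepoints = 3, seed = 42)
  f2 <- simulate_feature_table(c(A = 5, B = 5), timepoints = 3, seed = 42)
  expect_identical(f1, f2)
})
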