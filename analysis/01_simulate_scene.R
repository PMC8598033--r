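#!/usr/bin/env Rscript
# Simulate a demonstration microwell time-lapse: two phenotypes (a smooth
# "epithelial-like" class and a lobed, protrusive "mesenchymal-like"
# class), 6x6 wells, 10 one-minute frames, default camera noise, 10% dead
# cells revealed by the end-of-run viability frame. Writes the stack, the
# viability frame and the ground-truth table under results/demo_scene/.

suppressMessages(library(morphodyn))
seed <- 20260930L
out <- "results/demo_scene"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

plan <- scene_plan(grid_rows = 6, grid_cols = 6, frames = 10,
                   p_empty = 0.25, p_single = 0.65, p_multi = 0.10,
                   dead_fraction = 0.10, seed = seed)
phenos <- list(
  epithelial = phenotype_spec("epithelial", base_radius_um = 8,
                              amp_mean = c(0.06, 0.03, 0.01, 0, 0),
                              protrusion_rate = 0.05),
  mesenchymal = phenotype_spec("mesenchymal", base_radius_um = 7,
                               amp_mean = c(0.18, 0.10, 0.05, 0.02, 0.01),
                               protrusion_rate = 0.5,
                               protrusion_amplitude = 0.35))

scene <- simulate_timelapse(plan, phenos)
write_stack_tiff(scene$frames, file.path(out, "stack.tif"))
write_stack_tiff(scene$viability, file.path(out, "stack_viability.tif"))
write.csv(scene$truth, file.path(out, "truth.csv"), row.names = FALSE)

occ <- table(factor(scene$truth$occupancy, c("empty", "single", "multi")))
message(sprintf(
  "simulated %d wells over %d frames: %d empty, %d single, %d multi; %d dead",
  nrow(scene$truth), plan$frames, occ["empty"], occ["single"],
  occ["multi"], sum(scene$truth$alive %in% FALSE)))
message("wrote ", out, "/{stack.tif, stack_viability.tif, truth.csv}")
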