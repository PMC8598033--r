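#' Describe a synthetic cell phenotype
#'
#' A phenotype is a distribution over shape dynamics for the star-convex
#' boundary model: a base radius, harmonic lobe amplitudes a_k (k = 2..6)
#' drawn per cell around `amp_mean` with jitter `amp_sd`, a slow random
#' drift of the lobe phases, transient protrusion events, a fluorescence
#' intensity, and the in-plane rotation frequency of the suspended cell
#' (0.1 Hz by default, i.e. six full turns per one-minute frame interval).
#' Sub-phenotypes are within-class modes given as parameter offsets.
#'
#' @param name class label.
#' @param base_radius_um base cell radius, micrometres (> 0).
#' @param amp_mean length-5 numeric, mean lobe amplitudes for harmonics
#'   k = 2..6 (each in [0, 0.5): the boundary stays star-convex).
#' @param amp_sd jitter SD applied to each amplitude draw.
#' @param lobe_drift_rate phase drift SD, radians per minute.
#' @param protrusion_rate transient protrusion events per minute.
#' @param protrusion_amplitude protrusion height as a fraction of radius.
#' @param intensity_mean mean photon counts inside the cell.
#' @param rotation_freq_hz rotation frequency, rotations per second (>= 0).
#' @param subphenotypes non-empty list of named offset lists; each element
#'   may override/offset `base_radius_um`, `amp_mean`, `protrusion_rate`,
#'   `intensity_mean` (fields are added to the class values).
#' @return object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name,
                           base_radius_um = 8,
                           amp_mean = c(0.08, 0.05, 0.03, 0.02, 0.01),
                           amp_sd = 0.02,
                           lobe_drift_rate = 0.15,
                           protrusion_rate = 0.2,
                           protrusion_amplitude = 0.25,
                           intensity_mean = 3000,
                           rotation_freq_hz = 0.1,
                           subphenotypes = list(list())) {
  stopifnot(base_radius_um > 0, length(amp_mean) == 5L,
            all(amp_mean >= 0), all(amp_mean < 0.5),
            rotation_freq_hz >= 0, length(subphenotypes) >= 1L)
  structure(list(
    name = as.character(name), base_radius_um = base_radius_um,
    amp_mean = amp_mean, amp_sd = amp_sd,
    lobe_drift_rate = lobe_drift_rate,
    protrusion_rate = protrusion_rate,
    protrusion_amplitude = protrusion_amplitude,
    intensity_mean = intensity_mean,
    rotation_freq_hz = rotation_freq_hz,
    subphenotypes = subphenotypes
  ), class = "phenotype_spec")
}

apply_subphenotype <- function(spec, sub_id) {
  off <- spec$subphenotypes[[sub_id]]
  for (f in names(off)) {
    if (!f %in% c("base_radius_um", "amp_mean", "protrusion_rate",
                  "intensity_mean")) {
      stop("unknown sub-phenotype offset field: ", f)
    }
    spec[[f]] <- spec[[f]] + off[[f]]
  }
  stopifnot(spec$base_radius_um > 0)
  spec$amp_mean <- pmin(pmax(spec$amp_mean, 0), 0.499)
  spec
}

#' Plan a synthetic microwell scene
#'
#' Geometry and acquisition settings for one simulated field of view:
#' a `grid_rows` x `grid_cols` array of triangular microwells (side 40 um
#' as in the trapping device the simulator emulates), the per-well
#' occupancy distribution, the dead-cell fraction revealed by the
#' end-of-run viability stain, the camera noise model
#' (Poisson shot noise + Gaussian read noise + constant background) and
#' the frame schedule (one frame per minute by default). Well depth is
#' carried as metadata only: the render is a 2-D fluorescent silhouette.
#'
#' @param grid_rows,grid_cols well grid dimensions.
#' @param well_side_um triangular well side length (um), default 40.
#' @param well_pitch_um centre-to-centre well spacing (um), default 80.
#' @param well_depth_um recorded but unused (2-D projection), default 35.
#' @param pixel_size_um camera pixel size (um/px), default 0.5.
#' @param p_empty,p_single,p_multi occupancy probabilities (sum to 1);
#'   defaults give the >60% single-cell loading of the real device.
#' @param dead_fraction probability an occupied well's cell is dead.
#' @param noise_gaussian_sd camera read-noise SD (counts); 0 disables all
#'   noise (shot noise included), giving a deterministic render.
#' @param background_level constant background (counts).
#' @param frames number of timepoints (>= 1).
#' @param frame_interval_min minutes between frames, default 1.
#' @param max_pixels refuse to render images larger than this many pixels.
#' @param seed integer scene seed.
#' @return object of class `scene_plan`.
#' @export
scene_plan <- function(grid_rows = 4, grid_cols = 4,
                       well_side_um = 40, well_pitch_um = 80,
                       well_depth_um = 35,
                       pixel_size_um = 0.5,
                       p_empty = 0.25, p_single = 0.65, p_multi = 0.10,
                       dead_fraction = 0.1,
                       noise_gaussian_sd = 20,
                       background_level = 200,
                       frames = 10, frame_interval_min = 1,
                       max_pixels = 6e7,
                       seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, well_side_um > 0,
            well_pitch_um > 0, pixel_size_um > 0,
            frames >= 1, frame_interval_min > 0,
            dead_fraction >= 0, dead_fraction <= 1,
            p_empty >= 0, p_single >= 0, p_multi >= 0)
  if (abs(p_empty + p_single + p_multi - 1) > 1e-9) {
    stop("occupancy probabilities must sum to 1")
  }
  structure(as.list(environment()), class = "scene_plan")
}
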