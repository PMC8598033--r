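# Star-convex boundary model: r(theta, t) =
#   r0 * (1 + sum_k a_k * cos(k*(theta - omega*t) - phi_k(t))) + protrusions,
# with omega = 2*pi*rotation_freq_hz*60 radians per minute, phi_k a slow
# random walk (lobe drift), and protrusions as transient localized Gaussian
# bumps riding on the rotating boundary. r > 0 everywhere by construction
# (amplitude draws are rejected otherwise), so the outline is always a
# simple (non-self-intersecting) polygon.

#' Draw the per-cell shape-dynamics state
#'
#' Samples the realized amplitudes, initial phases, phase-drift path and
#' protrusion events for one cell over `frames` timepoints. The state makes
#' `simulate_cell_outline()` a deterministic function of time.
#'
#' @param spec a [phenotype_spec()].
#' @param frames number of frames the cell will be rendered for.
#' @param frame_interval_min minutes between frames.
#' @param seed integer seed for this cell.
#' @param max_retries bounded resampling attempts for amplitude draws that
#'   would let the radius reach zero.
#' @return object of class `cell_state`.
#' @export
cell_shape_state <- function(spec, frames, frame_interval_min = 1,
                             seed = 1L, max_retries = 100L) {
  with_seed(seed, {
    amps <- NULL
    for (i in seq_len(max_retries)) {
      a <- pmax(stats::rnorm(5L, spec$amp_mean, spec$amp_sd), 0)
      # worst-case radius is r0*(1 - sum(a)); keep strictly positive with
      # headroom for protrusion interplay
      if (sum(a) < 0.8 && all(a < 0.5)) { amps <- a; break }
    }
    if (is.null(amps)) stop("could not draw valid lobe amplitudes after ",
                            max_retries, " retries")
    phi0 <- stats::runif(5L, 0, 2 * pi)
    total_min <- frames * frame_interval_min
    # phase drift: Gaussian random walk per minute, one path per harmonic
    nsteps <- max(1L, ceiling(total_min))
    drift <- apply(matrix(stats::rnorm(5L * nsteps, 0, spec$lobe_drift_rate),
                          nrow = nsteps), 2L, cumsum)
    drift <- rbind(0, matrix(drift, nrow = nsteps))
    n_prot <- stats::rpois(1L, spec$protrusion_rate * total_min)
    prot <- data.frame(
      t0 = stats::runif(n_prot, 0, total_min),
      duration = stats::runif(n_prot, 2, 5),
      theta = stats::runif(n_prot, 0, 2 * pi),
      amp = spec$protrusion_amplitude * stats::runif(n_prot, 0.5, 1.5),
      width = stats::runif(n_prot, 0.25, 0.5)
    )
    structure(list(spec = spec, amps = amps, phi0 = phi0, drift = drift,
                   frame_interval_min = frame_interval_min,
                   total_min = total_min, protrusions = prot),
              class = "cell_state")
  })
}

# radius (um) at polar angles theta (radians, lab frame) and time t (minutes)
cell_radius <- function(state, theta, t) {
  spec <- state$spec
  omega <- 2 * pi * spec$rotation_freq_hz * 60  # rad / minute
  rot <- omega * t
  # interpolate drift path at time t (path is on a 1-minute grid)
  tt <- min(max(t, 0), state$total_min)
  i0 <- floor(tt); frac <- tt - i0
  row0 <- state$drift[i0 + 1L, ]
  row1 <- state$drift[min(i0 + 2L, nrow(state$drift)), ]
  phi <- state$phi0 + row0 + frac * (row1 - row0)
  r <- rep(1, length(theta))
  for (j in 1:5) {
    k <- j + 1L
    r <- r + state$amps[j] * cos(k * (theta - rot) - phi[j])
  }
  r <- r * spec$base_radius_um
  pr <- state$protrusions
  if (nrow(pr) > 0L) {
    for (i in seq_len(nrow(pr))) {
      dt <- t - pr$t0[i]
      if (dt < 0 || dt > pr$duration[i]) next
      envelope <- sin(pi * dt / pr$duration[i])  # rises then falls
      dth <- ((theta - pr$theta[i] - rot + pi) %% (2 * pi)) - pi
      r <- r + spec$base_radius_um * pr$amp[i] * envelope *
        exp(-dth^2 / (2 * pr$width[i]^2))
    }
  }
  if (any(r <= 0)) stop("cell radius collapsed to zero; invalid state")
  r
}

#' Simulate a cell outline at a given time
#'
#' Evaluates the star-convex boundary at `n_vertices` equally spaced polar
#' angles and returns the closed polygon in micrometre coordinates centred
#' on the cell.
#'
#' @param spec a [phenotype_spec()]; ignored if `state` is supplied.
#' @param t time in minutes (>= 0).
#' @param state optional [cell_shape_state()]; if `NULL` one is drawn from
#'   `seed` spanning `t` plus one frame.
#' @param n_vertices number of polygon vertices (>= 64).
#' @param seed seed used only when `state` is `NULL`.
#' @return data.frame with columns `x`, `y` (um), one row per vertex,
#'   vertices in counter-clockwise polar order (closed implicitly).
#' @export
simulate_cell_outline <- function(spec, t, state = NULL, n_vertices = 128L,
                                  seed = 1L) {
  stopifnot(t >= 0, n_vertices >= 64L)
  if (is.null(state)) state <- cell_shape_state(spec, frames = ceiling(t) + 1L,
                                                seed = seed)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- cell_radius(state, theta, t)
  data.frame(x = r * cos(theta), y = r * sin(theta))
}

# polygon area by the shoelace formula (um^2)
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
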