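# Well cropping, cell delineation, occupancy and viability filtering.
# Grid positions come from scene metadata/config (stage positions are
# programmed in the real instrument), so well location is arithmetic, not
# image registration.

#' Compute the well crop boxes for a grid image
#'
#' @param dims image dimensions `c(rows, cols)` in pixels, or an image
#'   matrix (its `dim` is used).
#' @param grid list/plan with `grid_rows`, `grid_cols`, `well_pitch_um`,
#'   `pixel_size_um` and optionally `origin_px = c(y0, x0)` (default 0,0).
#' @return data.frame, one row per well in row-major order: `well_id`,
#'   `row`, `col`, and the 0-based half-open pixel box `y0,y1,x0,x1`
#'   (side = pitch). Errors if any box exceeds the image.
#' @export
locate_wells <- function(dims, grid) {
  if (is.matrix(dims)) dims <- dim(dims)
  pitch_px <- grid$well_pitch_um / grid$pixel_size_um
  if (abs(pitch_px - round(pitch_px)) > 1e-6) {
    stop("well pitch must be an integer number of pixels")
  }
  pitch_px <- as.integer(round(pitch_px))
  origin <- if (!is.null(grid$origin_px)) as.integer(grid$origin_px) else c(0L, 0L)
  n <- grid$grid_rows * grid$grid_cols
  rows <- rep(seq_len(grid$grid_rows), each = grid$grid_cols)
  cols <- rep(seq_len(grid$grid_cols), times = grid$grid_rows)
  boxes <- data.frame(
    well_id = seq_len(n), row = rows, col = cols,
    y0 = origin[1] + (rows - 1L) * pitch_px,
    y1 = origin[1] + rows * pitch_px,
    x0 = origin[2] + (cols - 1L) * pitch_px,
    x1 = origin[2] + cols * pitch_px
  )
  bad <- boxes$y1 > dims[1] | boxes$x1 > dims[2] | boxes$y0 < 0 | boxes$x0 < 0
  if (any(bad)) {
    stop("well box(es) exceed the image for well_id: ",
         paste(utils::head(boxes$well_id[bad], 10L), collapse = ", "))
  }
  boxes
}

low_contrast <- function(m, min_contrast) {
  q <- stats::quantile(m, c(0.001, 0.999), names = FALSE)
  (q[2] - q[1]) < min_contrast
}

crop_box <- function(img, box) {
  img[(box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1, drop = FALSE]
}

#' Delineate the cell in a well crop
#'
#' Gaussian smoothing (sigma px), Otsu global threshold over the patch's
#' own intensity range (so the mask is invariant to constant offsets),
#' 3x3 binary opening then closing, hole filling, and retention of the
#' largest connected component (ties broken by lower scan order). An
#' empty mask is a valid result (nothing above threshold, or a
#' near-constant patch).
#'
#' @param crop numeric/integer matrix (grayscale patch).
#' @param sigma Gaussian smoothing SD in pixels, default 1.
#' @param min_contrast minimum robust intensity range (0.1%-99.9%
#'   quantiles, camera counts) for the patch to contain an object at all;
#'   low-contrast structure (well walls, background noise) falls below it.
#'   Default 250.
#' @return binary integer matrix of the crop's dimensions.
#' @export
delineate_cell <- function(crop, sigma = 1, min_contrast = 250) {
  m <- matrix(as.numeric(crop), nrow(crop), ncol(crop))
  rng <- range(m)
  if (diff(rng) < 1e-9 || low_contrast(m, min_contrast))
    return(matrix(0L, nrow(m), ncol(m)))
  img <- EBImage::Image((m - rng[1]) / diff(rng))
  if (sigma > 0) img <- EBImage::gblur(img, sigma = sigma)
  thr <- EBImage::otsu(img, range = c(0, 1))
  bw <- img > thr
  k <- EBImage::makeBrush(3, shape = "box")
  bw <- EBImage::closing(EBImage::opening(bw, k), k)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  labs <- as.integer(EBImage::imageData(lab))
  if (max(labs) == 0L) return(matrix(0L, nrow(m), ncol(m)))
  sizes <- tabulate(labs)
  keep <- which.max(sizes)  # which.max returns the first (lowest label) on ties
  matrix(as.integer(labs == keep), nrow(m), ncol(m))
}

#' Classify a well crop's occupancy
#'
#' Counts connected components of the pre-cleanup thresholded patch that
#' reach `min_area` pixels: none above threshold is `empty`, two or more
#' is `multi`, otherwise `single`.
#'
#' @param crop grayscale patch.
#' @param min_area minimum component area in pixels, default 30.
#' @param sigma smoothing used before thresholding (as in
#'   [delineate_cell()]).
#' @param min_contrast as in [delineate_cell()].
#' @return one of `"empty"`, `"single"`, `"multi"`.
#' @export
classify_occupancy <- function(crop, min_area = 30L, sigma = 1,
                               min_contrast = 250) {
  m <- matrix(as.numeric(crop), nrow(crop), ncol(crop))
  rng <- range(m)
  if (diff(rng) < 1e-9 || low_contrast(m, min_contrast)) return("empty")
  img <- EBImage::Image((m - rng[1]) / diff(rng))
  if (sigma > 0) img <- EBImage::gblur(img, sigma = sigma)
  thr <- EBImage::otsu(img, range = c(0, 1))
  lab <- EBImage::bwlabel(img > thr)
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  n_big <- sum(sizes >= min_area)
  if (n_big == 0L) "empty" else if (n_big >= 2L) "multi" else "single"
}

#' Segment a full synthetic/real time-lapse into per-cell series
#'
#' Crops every well in every frame, delineates masks, classifies per-frame
#' occupancy, and retains wells that are single-occupancy in at least
#' `1 - multi_tol` of frames with a non-empty mask in every retained
#' frame. A well transiently multi in more than `multi_tol` of frames is
#' disqualified ("only single cells" read conservatively).
#'
#' @param frames list of image matrices (one per timepoint).
#' @param grid grid geometry (see [locate_wells()]).
#' @param times_min timestamps, default `0:(nframes-1)`.
#' @param min_area occupancy component-size floor (px).
#' @param sigma smoothing sigma (px).
#' @param multi_tol maximum tolerated fraction of multi frames, default 0.2.
#' @return list of cell series: each has `cell_id` (= well_id), `row`,
#'   `col`, `box`, `times_min`, `crops` (list), `masks` (list),
#'   `occupancy` (per-frame), plus a `summary` data.frame attribute.
#' @export
segment_timelapse <- function(frames, grid, times_min = NULL,
                              min_area = 30L, sigma = 1, multi_tol = 0.2) {
  stopifnot(length(frames) >= 1L)
  if (is.null(times_min)) times_min <- seq_along(frames) - 1
  boxes <- locate_wells(dim(frames[[1]]), grid)
  cells <- list()
  summary_rows <- list()
  for (w in seq_len(nrow(boxes))) {
    box <- boxes[w, ]
    crops <- lapply(frames, crop_box, box = box)
    occ <- vapply(crops, classify_occupancy, "", min_area = min_area,
                  sigma = sigma)
    frac_multi <- mean(occ == "multi")
    frac_single <- mean(occ == "single")
    status <- if (all(occ == "empty")) "empty"
      else if (frac_multi > multi_tol) "multi"
      else if (frac_single >= 1 - multi_tol) "single"
      else "unstable"
    summary_rows[[w]] <- data.frame(
      well_id = box$well_id, status = status,
      frac_single = frac_single, frac_multi = frac_multi)
    if (status != "single") next
    masks <- lapply(crops, delineate_cell, sigma = sigma)
    keep_frames <- vapply(masks, function(mk) sum(mk) >= min_area, TRUE) &
      occ == "single"
    if (!any(keep_frames)) next
    cells[[length(cells) + 1L]] <- list(
      cell_id = box$well_id, row = box$row, col = box$col, box = box,
      times_min = times_min[keep_frames],
      crops = crops[keep_frames], masks = masks[keep_frames],
      occupancy = occ)
  }
  attr(cells, "summary") <- do.call(rbind, summary_rows)
  cells
}

#' Drop dead cells using the viability frame
#'
#' A well whose viability-channel crop shows signal above `threshold`
#' (robust per-well score: mean of the brightest 5% of pixels) is dropped.
#' With no viability frame the input passes through with a warning.
#'
#' @param cells list of cell series from [segment_timelapse()].
#' @param viability_frame image matrix or `NULL`.
#' @param grid grid geometry.
#' @param threshold counts; wells scoring above it are dead. If `NULL`,
#'   the threshold is set between the background (median well score) and
#'   the maximum score, at background + 0.25 * (max - background); with a
#'   `scene_plan` available prefer
#'   `background_level + intensity_mean / 4`.
#' @return the retained subset of `cells`; the number dropped is reported
#'   in a message and in the `n_dropped` attribute.
#' @export
filter_viability <- function(cells, viability_frame, grid, threshold = NULL) {
  if (is.null(viability_frame)) {
    warning("no viability frame supplied; keeping all cells")
    attr(cells, "n_dropped") <- 0L
    return(cells)
  }
  boxes <- locate_wells(dim(viability_frame), grid)
  score_well <- function(wid) {
    v <- as.numeric(crop_box(viability_frame, boxes[boxes$well_id == wid, ]))
    mean(sort(v, decreasing = TRUE)[seq_len(max(1L, round(0.05 * length(v))))])
  }
  scores <- vapply(vapply(cells, `[[`, 0, "cell_id"), score_well, 0)
  if (is.null(threshold)) {
    # background level and noise scale from the whole frame's pixels
    # (cells cover a few percent of the area, so the median and MAD are
    # background statistics even when every cell is dead); a well is dead
    # when its score clears both the noise floor and a quarter of the
    # brightest well's excursion
    v <- as.numeric(viability_frame)
    bg <- stats::median(v)
    noise <- stats::mad(v)
    all_scores <- vapply(boxes$well_id, score_well, 0)
    threshold <- bg + max(8 * noise, 0.25 * (max(all_scores) - bg))
  }
  dead <- scores > threshold
  kept <- cells[!dead]
  message(sprintf("viability filter: dropped %d of %d cells",
                  sum(dead), length(cells)))
  if (length(kept) == 0L) warning("all cells failed the viability filter")
  attr(kept, "summary") <- attr(cells, "summary")
  attr(kept, "n_dropped") <- sum(dead)
  kept
}
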