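#' Extract the 169-column feature table from segmented cell series
#'
#' One row per (cell, frame): 26 shape + 30 Zernike + 104 Haralick + 9
#' intensity features in manifest order. Frames whose mask is empty are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param cells list of cell series from [segment_timelapse()] (each with
#'   `cell_id`, `times_min`, `crops`, `masks`).
#' @param pixel_size um per pixel for the shape features.
#' @return data.frame `cell_id`, `time_min`, then the 169 manifest columns.
#' @export
extract_table <- function(cells, pixel_size = 1) {
  if (length(cells) == 0L) stop("extract_table: zero retained cells")
  man <- feature_manifest()$name
  rows <- list()
  meta <- list()
  dropped <- 0L
  for (cell in cells) {
    for (f in seq_along(cell$masks)) {
      mask <- cell$masks[[f]]
      if (sum(mask > 0) == 0L) { dropped <- dropped + 1L; next }
      crop <- cell$crops[[f]]
      v <- c(shape_features(mask, pixel_size),
             zernike_features(mask),
             haralick_features(crop, mask),
             intensity_features(crop, mask))
      rows[[length(rows) + 1L]] <- v
      meta[[length(meta) + 1L]] <- list(id = cell$cell_id,
                                        t = cell$times_min[f])
    }
  }
  if (length(rows) == 0L) stop("extract_table: no extractable frames")
  X <- do.call(rbind, rows)
  stopifnot(ncol(X) == 169L, identical(colnames(X), man))
  out <- cbind(
    data.frame(cell_id = vapply(meta, function(m) as.character(m$id), ""),
               time_min = vapply(meta, function(m) as.numeric(m$t), 0),
               stringsAsFactors = FALSE),
    as.data.frame(X))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  validate_feature_table(out)
  out
}
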