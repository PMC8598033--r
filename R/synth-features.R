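#' Simulate a per-cell, per-timepoint feature table with known labels
#'
#' Fast path for testing the machine-learning stages without rendering
#' images: draws cells from a two-class population with within-class
#' sub-phenotype modes, then emits one 169-column row per timepoint with
#' AR(1) temporal noise (marginal SD 1 per column, so all shifts are in
#' pooled within-class SD units).
#'
#' The generative model, per cell:
#' * class centre: class B is shifted by `effect_size` (pooled-SD units)
#'   on `n_informative` fixed manifest columns (the first
#'   `n_informative`); class A sits at the origin.
#' * sub-phenotype centre: within each class, component 1 is the class
#'   centre; component s > 1 adds an offset of Euclidean length
#'   `subph_offset` SD spread evenly over its own dedicated block of
#'   `n_subph_cols` columns (following the informative block), so all
#'   component centres are mutually separated by at least `subph_offset`
#'   pooled SD. Spreading the mode over several columns mirrors how a
#'   real morphological sub-phenotype co-varies across many features, and
#'   keeps the mode visible to variance-based dimension reduction.
#' * rows: centre + column-wise AR(1) noise over timepoints with
#'   coefficient `ar_coef` and stationary marginal SD 1.
#'
#' The defaults (4 components in class A, 3 in class B, 8-SD component
#' separation, 6-SD class separation) define the reference synthetic
#' population used throughout the package's experiments: two phenotypes at
#' least as separable as distinct epithelial/mesenchymal cell lines, with
#' seven planted morphological sub-phenotypes.
#'
#' @param n_cells_per_class named integer vector of cells per class
#'   (names must match `names(mixture)`), or a single integer applied to
#'   every class.
#' @param timepoints rows (minutes) per cell; timestamps 0..timepoints-1.
#' @param effect_size between-class mean shift in pooled within-class SD
#'   units, applied to the informative columns. Default 6.
#' @param mixture named integer vector: number of sub-phenotype components
#'   per class. Default `c(A = 4, B = 3)`.
#' @param seed integer seed.
#' @param ar_coef AR(1) coefficient of the within-cell temporal noise.
#' @param n_informative number of class-informative columns. Default 10.
#' @param subph_offset component-centre separation (Euclidean, pooled SD
#'   units). Default 8.
#' @param n_subph_cols columns spanned by each component offset. Default 10.
#' @return list with `features` (data.frame: `cell_id`, `time_min`, 169
#'   manifest columns) and `labels` (data.frame: `cell_id`, `class`,
#'   `subphenotype_id` — component id unique across classes).
#' @export
simulate_feature_table <- function(n_cells_per_class,
                                   timepoints,
                                   effect_size = 6,
                                   mixture = c(A = 4L, B = 3L),
                                   seed = 1L,
                                   ar_coef = 0.6,
                                   n_informative = 10L,
                                   subph_offset = 8,
                                   n_subph_cols = 10L) {
  stopifnot(timepoints >= 1, all(mixture >= 1L), length(mixture) >= 1L,
            !is.null(names(mixture)), abs(ar_coef) < 1)
  classes <- names(mixture)
  if (length(n_cells_per_class) == 1L && is.null(names(n_cells_per_class))) {
    n_cells_per_class <- stats::setNames(rep(n_cells_per_class,
                                             length(classes)), classes)
  }
  if (any(n_cells_per_class <= 0)) stop("cell counts must be positive")
  stopifnot(all(classes %in% names(n_cells_per_class)))
  man <- feature_manifest()$name
  p <- length(man)
  n_extra <- sum(pmax(mixture - 1L, 0L))
  if (n_informative + n_extra * n_subph_cols > p) {
    stop("too many structured columns")
  }

  # component centres: global component id 1..sum(mixture)
  comp_tab <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    data.frame(class = classes[ci], within = seq_len(mixture[ci]))
  }))
  comp_tab$component_id <- seq_len(nrow(comp_tab))
  extra_col <- n_informative
  centres <- matrix(0, nrow(comp_tab), p)
  for (r in seq_len(nrow(comp_tab))) {
    if (comp_tab$class[r] == classes[length(classes)] && length(classes) > 1L) {
      centres[r, seq_len(n_informative)] <- effect_size
    }
    if (comp_tab$within[r] > 1L) {
      block <- extra_col + seq_len(n_subph_cols)
      centres[r, block] <- subph_offset / sqrt(n_subph_cols)
      extra_col <- extra_col + n_subph_cols
    }
  }
  # first class carries no class shift; with >2 classes only the last is
  # shifted — the generator is a two-class design
  if (length(classes) > 2L) stop("the generator supports at most two classes")

  with_seed(substream_seed(seed, "features"), {
    n_total <- sum(n_cells_per_class[classes])
    rows_list <- vector("list", n_total)
    ids <- character(n_total)
    lab_class <- character(n_total)
    lab_comp <- integer(n_total)
    idx <- 0L
    for (cl in classes) {
      comps <- comp_tab[comp_tab$class == cl, ]
      ncells <- n_cells_per_class[[cl]]
      # near-equal allocation over components, in contiguous blocks
      comp_assign <- if (nrow(comps) == 1L) rep(comps$component_id, ncells)
      else comps$component_id[as.integer(cut(seq_len(ncells),
                                             breaks = nrow(comps),
                                             labels = FALSE))]
      for (i in seq_len(ncells)) {
        idx <- idx + 1L
        cid <- sprintf("%s_%04d", cl, i)
        comp <- comp_assign[i]
        mu <- centres[comp, ]
        # AR(1) noise, stationary marginal SD 1, per column
        eps <- matrix(stats::rnorm(timepoints * p), timepoints, p)
        if (timepoints > 1L) {
          sc <- sqrt(1 - ar_coef^2)
          for (tt in 2:timepoints) {
            eps[tt, ] <- ar_coef * eps[tt - 1L, ] + sc * eps[tt, ]
          }
        }
        rows_list[[idx]] <- sweep(eps, 2L, mu, `+`)
        ids[idx] <- cid
        lab_class[idx] <- cl
        lab_comp[idx] <- comp
      }
    }
    X <- do.call(rbind, rows_list)
    colnames(X) <- man
    features <- cbind(
      data.frame(cell_id = rep(ids, each = timepoints),
                 time_min = rep(0:(timepoints - 1L), times = n_total),
                 stringsAsFactors = FALSE),
      as.data.frame(X)
    )
    rownames(features) <- NULL
    labels <- data.frame(cell_id = ids, class = lab_class,
                         subphenotype_id = lab_comp, stringsAsFactors = FALSE)
    list(features = features, labels = labels)
  })
}

#' Collapse a feature table to one mean row per cell
#'
#' @param table feature table (manifest schema).
#' @return data.frame with one row per `cell_id`, columns = 169 manifest
#'   means, in first-appearance cell order.
#' @export
aggregate_cells <- function(table) {
  validate_feature_table(table)
  man <- feature_manifest()$name
  ids <- unique(table$cell_id)
  f <- factor(table$cell_id, levels = ids)
  out <- as.data.frame(
    lapply(table[man], function(col) as.vector(tapply(col, f, mean)))
  )
  out <- cbind(data.frame(cell_id = ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
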