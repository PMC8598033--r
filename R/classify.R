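# Supervised phenotype classification: cell-level shuffled 70/30 holdout,
# optional time limit and minority subsampling, leakage-free z-score +
# PCA preprocessing fitted on the training rows only, discrete AdaBoost
# with depth-1 decision stumps, per-cell label aggregation, and Eq-style
# precision/recall/f1 scoring averaged over repeats.

#' Plan a classification experiment
#'
#' @param train_fraction fraction of cells assigned to training (default
#'   0.70; the split is per-class stratified at the cell level so all
#'   timepoint rows of a cell stay on one side).
#' @param time_limit_min keep only rows with `time_min` strictly smaller
#'   than this (minutes); `Inf` keeps everything.
#' @param target_class label coded 1 (the "target"/minority phenotype);
#'   the other class is coded 0.
#' @param ratio target-to-general training-example ratio (rows), e.g.
#'   `1/1500`, or `NULL` for no subsampling.
#' @param repeats number of shuffled-holdout repetitions, default 30.
#' @param n_components PCA components retained, default 14.
#' @param n_rounds boosting rounds, default 100.
#' @param aggregate per-cell label aggregation: `"majority_vote"`
#'   (default), `"mean_score"`, or `"per_row"`.
#' @param seed integer seed.
#' @return object of class `experiment_plan`.
#' @export
experiment_plan <- function(train_fraction = 0.70, time_limit_min = Inf,
                            target_class = NULL, ratio = NULL,
                            repeats = 30L, n_components = 14L,
                            n_rounds = 100L,
                            aggregate = "majority_vote", seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, repeats >= 1,
            n_components >= 1, n_rounds >= 1)
  if (!is.null(ratio)) stopifnot(ratio > 0, ratio <= 1)
  structure(as.list(environment()), class = "experiment_plan")
}

#' Split cells into training and testing sets
#'
#' Cell-level, per-class stratified: within each class the cells are
#' shuffled, `n_c - floor((1 - fraction) * n_c)` go to training (the
#' fractional remainder cell goes to the training side) and the rest to
#' testing. No cell id ever appears on both sides.
#'
#' @param cell_ids character vector of cell ids (one entry per cell).
#' @param classes class label per cell (same length).
#' @param train_fraction training fraction.
#' @param seed integer seed.
#' @return list with `train` and `test` character vectors of cell ids.
#' @export
split_by_cell <- function(cell_ids, classes, train_fraction = 0.7, seed = 1L) {
  stopifnot(length(cell_ids) == length(classes), !anyDuplicated(cell_ids))
  tab <- table(classes)
  if (any(tab < 2L)) {
    stop("each class needs at least 2 cells; got: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  with_seed(seed, {
    train <- character(0)
    for (cl in names(tab)) {
      ids <- sample(cell_ids[classes == cl])
      n_test <- floor((1 - train_fraction) * length(ids))
      train <- c(train, ids[seq_len(length(ids) - n_test)])
    }
    list(train = train, test = setdiff(cell_ids, train))
  })
}

#' Apply a strict time limit to a feature table
#'
#' Keeps rows with `time_min` strictly smaller than `T` ("measurements at
#' time points smaller than the time limit"). `T = 1` on a one-frame-per-
#' minute series starting at 0 keeps only the t = 0 rows.
#'
#' @param table feature table.
#' @param T time limit in minutes (`Inf` = identity).
#' @return the filtered table; errors if nothing remains.
#' @export
apply_time_limit <- function(table, T) {
  if (is.infinite(T)) return(table)
  out <- table[table$time_min < T, , drop = FALSE]
  if (nrow(out) == 0L) stop("time limit T = ", T, " leaves no rows")
  out
}

#' Subsample the target class in a training table to a fixed example ratio
#'
#' Reduces the target-class training rows so that
#' (#target rows)/(#general rows) equals `ratio` within one row. Whole
#' cells are removed first (in shuffled order); the last retained cell is
#' truncated row-wise (earliest timepoints kept) to hit the budget.
#' The test set is never touched.
#'
#' @param train_rows training feature table with a `label01` column
#'   (1 = target).
#' @param ratio requested target/general row ratio.
#' @param seed integer seed.
#' @return the subsampled training table.
#' @export
subsample_target <- function(train_rows, ratio, seed = 1L) {
  n_gen <- sum(train_rows$label01 == 0L)
  n_tgt <- sum(train_rows$label01 == 1L)
  stopifnot(n_gen > 0L)
  if (ratio > n_tgt / n_gen + 1e-12) {
    stop("requested ratio exceeds the current target/general ratio")
  }
  budget <- round(ratio * n_gen)
  if (budget < 1L) stop("ratio ", format(ratio), " leaves 0 target rows")
  tgt <- train_rows[train_rows$label01 == 1L, , drop = FALSE]
  with_seed(seed, {
    ids <- sample(unique(tgt$cell_id))
    keep <- rep(FALSE, nrow(tgt))
    used <- 0L
    for (id in ids) {
      rows <- which(tgt$cell_id == id)
      rows <- rows[order(tgt$time_min[rows])]
      take <- min(length(rows), budget - used)
      if (take <= 0L) break
      keep[rows[seq_len(take)]] <- TRUE
      used <- used + take
    }
    rbind(train_rows[train_rows$label01 == 0L, , drop = FALSE], tgt[keep, , drop = FALSE])
  })
}

#' Fit the normalization + PCA preprocessor on training rows only
#'
#' Per-feature z-scoring (constant columns get SD 1, so they map to 0)
#' followed by projection onto the top `n_components` principal
#' directions of the standardized training matrix. The returned parameters
#' are a pure function of the training rows; the same affine + linear
#' transform is applied verbatim to test rows.
#'
#' @param X numeric matrix (training rows x features).
#' @param n_components components to retain.
#' @return object of class `preproc_params` with `mean`, `sd`, `rotation`
#'   (orthonormal columns) and `explained_var` (fractions).
#' @export
fit_preprocessor <- function(X, n_components = 14L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= n_components + 1L)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-10)
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds the data rank (", rank, ")")
  }
  structure(list(
    mean = mu, sd = sdv,
    rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
    explained_var = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
    n_components = n_components
  ), class = "preproc_params")
}

#' Apply fitted preprocessing parameters
#' @param pp a `preproc_params` object.
#' @param X numeric matrix (rows x original features).
#' @return matrix rows x n_components.
#' @export
preproc_transform <- function(pp, X) {
  Z <- sweep(sweep(as.matrix(X), 2L, pp$mean), 2L, pp$sd, `/`)
  Z %*% pp$rotation
}

# exhaustive best weighted stump over all features; thresholds are the
# midpoints of sorted unique values. Vectorized cumulative-sum scan.
# Tie-break: lowest weighted error, then lowest feature index, then lowest
# threshold, then polarity +1 ("predict 1 above threshold") first.
best_stump <- function(X, y, w, ord = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(ord)) ord <- lapply(seq_len(p), function(j) order(X[, j]))
  best <- list(err = Inf)
  for (j in seq_len(p)) {
    o <- ord[[j]]
    xs <- X[o, j]; ys <- y[o]; ws <- w[o]
    s1 <- cumsum(ws * ys); s0 <- cumsum(ws * (1 - ys))
    T1 <- s1[n]; T0 <- s0[n]
    valid <- which(xs[-n] < xs[-1L])
    if (length(valid) == 0L) next
    err_plus <- s1[valid] + (T0 - s0[valid])   # predict 1 where x > thr
    err_minus <- (T1 + T0) - err_plus          # predict 1 where x <= thr
    bp <- which.min(err_plus); bm <- which.min(err_minus)
    for (cand in list(list(e = err_plus[bp], i = valid[bp], pol = 1L),
                      list(e = err_minus[bm], i = valid[bm], pol = -1L))) {
      thr <- (xs[cand$i] + xs[cand$i + 1L]) / 2
      if (cand$e < best$err - 1e-15 ||
          (abs(cand$e - best$err) <= 1e-15 && j == best$feature &&
           thr < best$threshold - 1e-15)) {
        best <- list(err = cand$e, feature = j, threshold = thr,
                     polarity = cand$pol)
      }
    }
  }
  if (!is.finite(best$err)) return(NULL)
  best
}

stump_predict01 <- function(X, feature, threshold, polarity) {
  above <- X[, feature] > threshold
  if (polarity > 0) as.integer(above) else as.integer(!above)
}

#' Fit a discrete AdaBoost ensemble of decision stumps
#'
#' Freund-Schapire two-class AdaBoost with depth-1 stumps: uniform initial
#' weights; each round the stump (feature, threshold, polarity) minimizing
#' the weighted 0-1 error over all midpoint thresholds is selected;
#' alpha_t = 0.5 * log((1 - eps_t)/eps_t); multiplicative weight update and
#' renormalization. Boosting stops early when eps_t >= 0.5 (stump
#' discarded) or eps_t = 0 (stump kept with alpha capped).
#'
#' @param X numeric matrix (rows x features).
#' @param y labels in {0, 1}.
#' @param n_rounds maximum boosting rounds, default 100.
#' @return object of class `boost_model`: data.frame `stumps` with
#'   `feature`, `threshold`, `polarity`, `alpha`, `eps`.
#' @export
fit_adaboost <- function(X, y, n_rounds = 100L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), n_rounds >= 1L)
  if (length(unique(y)) < 2L) stop("fit_adaboost: single-class labels")
  n <- nrow(X)
  w <- rep(1 / n, n)
  ysign <- 2 * y - 1
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  stumps <- vector("list", n_rounds)
  used <- 0L
  for (t in seq_len(n_rounds)) {
    st <- best_stump(X, y, w, ord)
    if (is.null(st) || st$err >= 0.5) break
    eps <- st$err
    alpha <- if (eps <= 0) 0.5 * log((1 - 1e-12) / 1e-12)
      else 0.5 * log((1 - eps) / eps)
    used <- used + 1L
    stumps[[used]] <- data.frame(feature = st$feature,
                                 threshold = st$threshold,
                                 polarity = st$polarity,
                                 alpha = alpha, eps = eps)
    if (eps <= 0) break
    h <- 2 * stump_predict01(X, st$feature, st$threshold, st$polarity) - 1
    w <- w * exp(-alpha * ysign * h)
    w <- w / sum(w)
  }
  if (used == 0L) stop("fit_adaboost: no stump with weighted error < 0.5")
  structure(list(stumps = do.call(rbind, stumps[seq_len(used)])),
            class = "boost_model")
}

#' Boosted margin (sum of alpha-weighted stump votes in {-1, +1})
#' @param model a `boost_model`.
#' @param X numeric matrix.
#' @return numeric vector of margins; the predicted label is 1 where the
#'   margin is > 0 and 0 otherwise.
#' @export
boost_margin <- function(model, X) {
  X <- as.matrix(X)
  s <- model$stumps
  out <- numeric(nrow(X))
  for (t in seq_len(nrow(s))) {
    h <- 2 * stump_predict01(X, s$feature[t], s$threshold[t], s$polarity[t]) - 1
    out <- out + s$alpha[t] * h
  }
  out
}

#' @rdname boost_margin
#' @export
predict_boost <- function(model, X) as.integer(boost_margin(model, X) > 0)

#' Aggregate row-level predictions to per-cell labels
#'
#' @param margins row-level boosted margins.
#' @param cell_ids cell id per row.
#' @param aggregate `"majority_vote"` (fraction of rows predicted 1 must
#'   exceed 1/2; exact ties go to the general class 0), `"mean_score"`
#'   (sign of the mean margin; ties to 0), or `"per_row"` (no
#'   aggregation: returns one label per row).
#' @return data.frame `cell_id`, `pred` (and `time_index` for per_row).
#' @export
predict_cells <- function(margins, cell_ids,
                          aggregate = c("majority_vote", "mean_score", "per_row")) {
  aggregate <- match.arg(aggregate)
  row_pred <- as.integer(margins > 0)
  if (aggregate == "per_row") {
    return(data.frame(cell_id = cell_ids, pred = row_pred,
                      stringsAsFactors = FALSE))
  }
  ids <- unique(cell_ids)
  f <- factor(cell_ids, levels = ids)
  pred <- if (aggregate == "majority_vote") {
    as.integer(tapply(row_pred, f, mean) > 0.5)
  } else {
    as.integer(tapply(margins, f, mean) > 0)
  }
  data.frame(cell_id = ids, pred = unname(pred), stringsAsFactors = FALSE)
}

#' Per-class precision, recall and f1
#'
#' Precision = TP/(TP+FP) (0 when the denominator is 0, which is logged),
#' recall = TP/(TP+FN), f1 = 2PR/(P+R) — the harmonic-mean formula.
#'
#' @param pred predicted labels in {0, 1}.
#' @param truth true labels in {0, 1}.
#' @return data.frame with one row per class (0 and 1): `class`, `TP`,
#'   `FP`, `FN`, `TN`, `precision`, `recall`, `f1`, `support`.
#' @export
score_predictions <- function(pred, truth) {
  stopifnot(length(pred) == length(truth),
            all(pred %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  out <- lapply(c(0L, 1L), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- sum(pred != cl & truth != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, TP = tp, FP = fp, FN = fn, TN = tn,
               precision = prec, recall = rec, f1 = f1, support = tp + fn)
  })
  do.call(rbind, out)
}

#' Run the full repeated-holdout classification experiment
#'
#' Per repeat: reshuffle and split cells (stratified, cell-level), apply
#' the time limit, subsample the target class to the requested training
#' ratio, fit the z-score + PCA preprocessor on the training rows only,
#' transform both sides, fit AdaBoost, predict per cell, score. Metrics
#' are reported per class as mean and SD over repeats.
#'
#' @param table feature table (manifest schema).
#' @param labels data.frame `cell_id`, `class` (exactly two classes).
#' @param plan an [experiment_plan()].
#' @return list of class `experiment_report`: `plan`, `per_repeat`
#'   (data.frame), `summary` (per-class means/SDs).
#' @export
run_experiment <- function(table, labels, plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  validate_feature_table(table)
  classes <- sort(unique(labels$class))
  stopifnot(length(classes) == 2L)
  target <- if (is.null(plan$target_class)) classes[2L] else plan$target_class
  stopifnot(target %in% classes)
  man <- feature_manifest()$name
  lab_map <- stats::setNames(as.integer(labels$class == target), labels$cell_id)
  table$label01 <- unname(lab_map[table$cell_id])
  if (anyNA(table$label01)) stop("labels missing for some cells in the table")
  table <- apply_time_limit(table, plan$time_limit_min)
  per_repeat <- vector("list", plan$repeats)
  for (r in seq_len(plan$repeats)) {
    res <- tryCatch(
      run_one_repeat(table, labels, plan, target, man,
                     seed = substream_seed(plan$seed, "repeat", r)),
      error = function(e) stop("repeat ", r, ": ", conditionMessage(e)))
    res$repeat_id <- r
    per_repeat[[r]] <- res
  }
  per_repeat <- do.call(rbind, per_repeat)
  agg <- function(cl, col, f) f(per_repeat[per_repeat$class == cl, col])
  summary <- do.call(rbind, lapply(c(0L, 1L), function(cl) data.frame(
    class = cl,
    label = if (cl == 1L) target else setdiff(classes, target),
    precision_mean = agg(cl, "precision", mean),
    precision_sd = agg(cl, "precision", stats::sd),
    recall_mean = agg(cl, "recall", mean),
    recall_sd = agg(cl, "recall", stats::sd),
    f1_mean = agg(cl, "f1", mean),
    f1_sd = agg(cl, "f1", stats::sd),
    support_mean = agg(cl, "support", mean))))
  structure(list(plan = plan, per_repeat = per_repeat, summary = summary),
            class = "experiment_report")
}

run_one_repeat <- function(table, labels, plan, target, man, seed) {
  sp <- split_by_cell(labels$cell_id, labels$class, plan$train_fraction,
                      seed = substream_seed(seed, "split"))
  train <- table[table$cell_id %in% sp$train, , drop = FALSE]
  test <- table[table$cell_id %in% sp$test, , drop = FALSE]
  if (!is.null(plan$ratio)) {
    train <- subsample_target(train, plan$ratio,
                              seed = substream_seed(seed, "subsample"))
  }
  pp <- fit_preprocessor(as.matrix(train[man]), plan$n_components)
  Xtr <- preproc_transform(pp, as.matrix(train[man]))
  Xte <- preproc_transform(pp, as.matrix(test[man]))
  model <- fit_adaboost(Xtr, train$label01, plan$n_rounds)
  margins <- boost_margin(model, Xte)
  pc <- predict_cells(margins, test$cell_id, plan$aggregate)
  truth <- if (plan$aggregate == "per_row") test$label01
    else unname(stats::setNames(as.integer(labels$class == target),
                                labels$cell_id)[pc$cell_id])
  sc <- score_predictions(pc$pred, truth)
  sc
}
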