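# Supervised protocol: splitting, time limits, subsampling, preprocessing
# (leakage), AdaBoost (oracle + guarantees), aggregation, scoring, repeats.

two_class_labels <- function(nA, nB) {
  data.frame(cell_id = c(sprintf("A%03d", seq_len(nA)),
                         sprintf("B%03d", seq_len(nB))),
             class = c(rep("A", nA), rep("B", nB)),
             stringsAsFactors = FALSE)
}

test_that("cell-level split is stratified, exact, and leak-free", {
  lab <- two_class_labels(500, 500)
  sp <- split_by_cell(lab$cell_id, lab$class, 0.7, seed = 1)
  expect_length(sp$train, 700)
  expect_length(sp$test, 300)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), lab$cell_id)
  # per-class counts
  expect_equal(sum(grepl("^A", sp$train)), 350)
  lab2 <- two_class_labels(10, 10)
  sp2 <- split_by_cell(lab2$cell_id, lab2$class, 0.7, seed = 2)
  expect_equal(sum(grepl("^A", sp2$train)), 7)
  expect_equal(sum(grepl("^B", sp2$train)), 7)
  expect_error(split_by_cell(c("a", "b"), c("A", "B"), 0.7), "at least 2")
})

test_that("time limit keeps strictly earlier rows only", {
  tab <- data.frame(cell_id = rep("c1", 60), time_min = 0:59)
  expect_equal(nrow(apply_time_limit(tab, 1)), 1)    # only t = 0
  expect_equal(apply_time_limit(tab, 1)$time_min, 0)
  expect_equal(nrow(apply_time_limit(tab, 10)), 10)
  expect_identical(apply_time_limit(tab, Inf), tab)
  expect_error(apply_time_limit(tab[tab$time_min > 5, ], 2), "no rows")
})

test_that("target subsampling hits the requested row ratio within one row", {
  tab <- data.frame(
    cell_id = c(rep(sprintf("G%04d", 1:1500), each = 20),
                rep(sprintf("T%03d", 1:10), each = 20)),
    time_min = rep(0:19, 1510),
    label01 = c(rep(0L, 30000), rep(1L, 200)))
  out <- subsample_target(tab, 1 / 1500, seed = 3)
  expect_equal(sum(out$label01 == 1L), 20)  # 30000 / 1500
  expect_equal(sum(out$label01 == 0L), 30000)
  # whole-cell-first: the kept rows span exactly one target cell
  expect_equal(length(unique(out$cell_id[out$label01 == 1L])), 1L)
  out2 <- subsample_target(tab, 200 / 30000, seed = 3)
  expect_equal(nrow(out2), nrow(tab))  # ratio at current value: identity size
  expect_error(subsample_target(tab, 1 / 1e7), "0 target rows")
  expect_error(subsample_target(tab, 0.5), "exceeds")
})

test_that("preprocessor is a pure function of the training rows", {
  set.seed(4)
  Xtr <- matrix(rnorm(200 * 30), 200)
  pp1 <- fit_preprocessor(Xtr, 5)
  pp2 <- fit_preprocessor(Xtr, 5)
  expect_identical(pp1, pp2)
  # transformed training data: mean ~ 0, uncorrelated components
  P <- preproc_transform(pp1, Xtr)
  expect_lt(max(abs(colMeans(P))), 1e-10)
  cv <- crossprod(sweep(P, 2, colMeans(P))) / (nrow(P) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_true(all(diff(pp1$explained_var) <= 1e-12))
  # orthonormal basis
  expect_equal(unname(crossprod(pp1$rotation)), diag(5), tolerance = 1e-10)
  expect_error(fit_preprocessor(Xtr[, 1:3], 5), "rank|rows")
})

test_that("constant columns are tolerated and full rank reconstructs exactly", {
  set.seed(5)
  X <- cbind(matrix(rnorm(50 * 4), 50), 7)  # constant 5th column
  pp <- fit_preprocessor(X, 4)
  P <- preproc_transform(pp, X)
  expect_equal(dim(P), c(50L, 4L))
  # full-component projection preserves all variance (reconstruction = 0)
  Z <- sweep(sweep(X, 2, pp$mean), 2, pp$sd, `/`)
  pc <- stats::prcomp(Z, center = FALSE)
  recon <- pc$x %*% t(pc$rotation)
  expect_equal(recon, Z, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("round-1 stump equals the exhaustive oracle on 20 hand points", {
  set.seed(6)
  X <- cbind(c(rnorm(10, -1), rnorm(10, 1)), rnorm(20), runif(20, -3, 3))
  y <- rep(c(0L, 1L), each = 10)
  w <- rep(1 / 20, 20)
  got <- morphodyn:::best_stump(X, y, w)
  want <- oracle_stump(X, y, w)
  expect_equal(got$err, want$err, tolerance = 1e-12)
  expect_equal(got$feature, want$feature)
  expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  # round-1 alpha from the oracle error
  model <- fit_adaboost(X, y, n_rounds = 1)
  expect_equal(model$stumps$alpha[1],
               0.5 * log((1 - want$err) / want$err), tolerance = 1e-12)
})

test_that("AdaBoost: separable data, error guarantees, exponential bound", {
  # 1-D perfectly separable: zero training error after round 1
  X <- matrix(c(1:5, 11:15), ncol = 1)
  y <- rep(c(0L, 1L), each = 5)
  m <- fit_adaboost(X, y, n_rounds = 10)
  expect_equal(nrow(m$stumps), 1L)
  expect_identical(predict_boost(m, X), y)
  # harder data: every accepted stump beats 0.5, and the training error
  # respects the exponential bound prod 2*sqrt(eps(1-eps))
  set.seed(7)
  X2 <- matrix(rnorm(300 * 5), 300)
  y2 <- as.integer(X2[, 1] + 0.8 * X2[, 3] + rnorm(300, 0, 0.7) > 0)
  m2 <- fit_adaboost(X2, y2, n_rounds = 40)
  expect_true(all(m2$stumps$eps < 0.5))
  train_err <- mean(predict_boost(m2, X2) != y2)
  bound <- prod(2 * sqrt(m2$stumps$eps * (1 - m2$stumps$eps)))
  expect_lte(train_err, bound + 1e-12)
  expect_error(fit_adaboost(X2, rep(1L, 300)), "single-class")
})

test_that("per-cell aggregation rules and tie-breaking", {
  margins <- c(1, 1, -1, 1, -2, -0.5, -0.5, 0.5)
  cells <- c("a", "a", "a", "a", "b", "b", "c", "c")
  mv <- predict_cells(margins, cells, "majority_vote")
  expect_identical(mv$pred, c(1L, 0L, 0L))  # c ties 1-1 -> general class 0
  ms <- predict_cells(margins, cells, "mean_score")
  expect_identical(ms$pred[1], 1L)
  expect_identical(ms$pred[2], 0L)
  expect_identical(ms$pred[3], 0L)  # mean margin 0 -> class 0
  pr <- predict_cells(margins, cells, "per_row")
  expect_equal(nrow(pr), 8)
  expect_error(predict_cells(margins, cells, "weird"))
})

test_that("scoring matches hand counts and a brute-force oracle", {
  # TP=9, FP=1, FN=1 for class 1 -> precision = recall = f1 = 0.9
  truth <- c(rep(1L, 10), rep(0L, 10))
  pred <- truth
  pred[10] <- 0L   # one false negative for class 1
  pred[20] <- 1L   # one false positive for class 1
  sc <- score_predictions(pred, truth)
  r1 <- sc[sc$class == 1, ]
  expect_equal(r1$TP, 9); expect_equal(r1$FP, 1); expect_equal(r1$FN, 1)
  expect_equal(r1$precision, 0.9)
  expect_equal(r1$recall, 0.9)
  expect_equal(r1$f1, 0.9)
  # perfect prediction
  sp <- score_predictions(truth, truth)
  expect_true(all(sp$precision == 1 & sp$recall == 1 & sp$f1 == 1))
  # random instance vs direct counting oracle
  set.seed(8)
  t2 <- rbinom(200, 1, 0.4); p2 <- rbinom(200, 1, 0.5)
  sc2 <- score_predictions(p2, t2)
  for (cl in 0:1) {
    tp <- sum(p2 == cl & t2 == cl); fp <- sum(p2 == cl & t2 != cl)
    fn <- sum(p2 != cl & t2 == cl)
    prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    expect_equal(sc2$f1[sc2$class == cl],
                 ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0),
                 tolerance = 1e-12)
  }
})

test_that("run_experiment is deterministic and collects 30-repeat summaries", {
  ft <- simulate_feature_table(c(A = 20, B = 20), timepoints = 4,
                               mixture = c(A = 1L, B = 1L), seed = 10)
  plan <- experiment_plan(repeats = 5, n_rounds = 20, seed = 123)
  r1 <- run_experiment(ft$features, ft$labels, plan)
  r2 <- run_experiment(ft$features, ft$labels, plan)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(nrow(r1$per_repeat), 5 * 2)  # per repeat x class
  expect_true(all(c("precision_mean", "recall_sd", "f1_mean") %in%
                    names(r1$summary)))
})

test_that("preprocessing never sees the test rows (no leakage)", {
  ft <- simulate_feature_table(c(A = 30, B = 30), timepoints = 3,
                               mixture = c(A = 1L, B = 1L), seed = 11)
  man <- feature_manifest()$name
  sp <- split_by_cell(ft$labels$cell_id, ft$labels$class, 0.7, seed = 5)
  train <- ft$features[ft$features$cell_id %in% sp$train, ]
  pp1 <- fit_preprocessor(as.matrix(train[man]), 14)
  # permute, perturb, or drop the test rows: parameters are bit-identical
  pp2 <- fit_preprocessor(as.matrix(train[sample(nrow(train)), man][order(sample(nrow(train))), , drop = FALSE]), 14)
  expect_identical(pp1$mean, pp2$mean)
  expect_identical(pp1$sd, pp2$sd)
})

test_that("null-effect population scores near chance", {
  ft <- simulate_feature_table(c(A = 40, B = 40), timepoints = 2,
                               effect_size = 0, mixture = c(A = 1L, B = 1L),
                               seed = 12)
  plan <- experiment_plan(repeats = 6, n_rounds = 15, n_components = 5,
                          seed = 77)
  rep <- run_experiment(ft$features, ft$labels, plan)
  f1s <- rep$summary$f1_mean
  expect_true(all(f1s > 0.2 & f1s < 0.8))  # chance-level, wide MC band
})

test_that("more observation time does not substantially hurt accuracy", {
  ft <- simulate_feature_table(c(A = 40, B = 40), timepoints = 20,
                               effect_size = 1.2, mixture = c(A = 1L, B = 1L),
                               seed = 13)
  base <- experiment_plan(repeats = 8, n_rounds = 30, seed = 5)
  p1 <- base; p1$time_limit_min <- 1
  p20 <- base; p20$time_limit_min <- 20
  f1_1 <- run_experiment(ft$features, ft$labels, p1)$summary
  f1_20 <- run_experiment(ft$features, ft$labels, p20)$summary
  sd1 <- max(f1_1$f1_sd)
  expect_gte(mean(f1_20$f1_mean), mean(f1_1$f1_mean) - sd1)
})

test_that("f1 variance across repeats grows as the minority ratio shrinks", {
  # at moderate separability, starving the minority class of training
  # examples makes the repeated-holdout score noticeably noisier
  ft <- simulate_feature_table(c(A = 300, B = 40), timepoints = 10,
                               effect_size = 3, mixture = c(A = 1L, B = 1L),
                               seed = 21)
  base <- experiment_plan(target_class = "B", repeats = 10, n_rounds = 50,
                          seed = 31)
  rich <- base; rich$ratio <- 1 / 10
  poor <- base; poor$ratio <- 1 / 1500
  sd_rich <- run_experiment(ft$features, ft$labels, rich)$summary
  sd_poor <- run_experiment(ft$features, ft$labels, poor)$summary
  expect_gte(sd_poor$f1_sd[sd_poor$class == 1],
             sd_rich$f1_sd[sd_rich$class == 1])
})
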