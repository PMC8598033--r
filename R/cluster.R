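# Unsupervised sub-phenotype discovery: Lloyd k-means minimizing the
# within-cluster sum of squares (WCSS), the entropy-based homogeneity
# score of a clustering against known labels, per-cluster purity, and
# selection of k under a per-cluster purity constraint.

#' Lloyd k-means with random restarts
#'
#' Plain Lloyd iterations: assign every point to the nearest mean by
#' squared Euclidean distance, recompute the means, repeat until the
#' assignment is a fixed point, the WCSS improvement falls below `tol`,
#' or `max_iter` is reached. The best of `n_init` random initializations
#' (k distinct data points each) by final WCSS is returned. An empty
#' cluster is repaired by reseeding it at the point currently farthest
#' from its assigned centroid. WCSS is non-increasing across iterations
#' (asserted).
#'
#' @param X numeric matrix (points x dims).
#' @param k number of clusters (<= number of distinct points).
#' @param seed integer seed.
#' @param n_init random restarts, default 10.
#' @param max_iter maximum Lloyd iterations per restart, default 300.
#' @param tol WCSS improvement tolerance, default 1e-6.
#' @return object of class `cluster_result`: `assignments` (1..k),
#'   `centroids`, `k`, `wcss`, `iterations`, `converged`.
#' @export
kmeans_lloyd <- function(X, k, seed = 1L, n_init = 10L, max_iter = 300L,
                         tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  ndistinct <- nrow(unique(X))
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")")
  if (k > ndistinct) stop("k (", k, ") exceeds the number of distinct points")
  best <- NULL
  for (init in seq_len(n_init)) {
    res <- with_seed(substream_seed(seed, "kmeans_init", init),
                     lloyd_once(X, k, max_iter, tol))
    if (is.null(best) || res$wcss < best$wcss) best <- res
  }
  structure(c(best, list(k = k, n_init = n_init)), class = "cluster_result")
}

lloyd_once <- function(X, k, max_iter, tol) {
  n <- nrow(X)
  # k distinct random points as initial means
  centers <- X[sample(n), , drop = FALSE]
  centers <- unique(centers)[seq_len(k), , drop = FALSE]
  xsq <- rowSums(X^2)
  assign_pts <- function(centers) {
    d2 <- outer(xsq, rowSums(centers^2), `+`) - 2 * X %*% t(centers)
    list(a = max.col(-d2, ties.method = "first"),
         d = pmax(d2[cbind(seq_len(n), max.col(-d2, ties.method = "first"))], 0))
  }
  prev_wcss <- Inf
  asg <- assign_pts(centers)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # repair empty clusters: reseed at the point farthest from its centroid
    for (cl in seq_len(k)) {
      if (!any(asg$a == cl)) {
        far <- which.max(asg$d)
        centers[cl, ] <- X[far, ]
        asg$a[far] <- cl
        asg$d[far] <- 0
      }
    }
    for (cl in seq_len(k)) {
      centers[cl, ] <- colMeans(X[asg$a == cl, , drop = FALSE])
    }
    new_asg <- assign_pts(centers)
    wcss <- sum(new_asg$d)
    if (wcss > prev_wcss + 1e-8 * max(1, prev_wcss)) {
      stop("internal error: WCSS increased across a Lloyd iteration")
    }
    if (identical(new_asg$a, asg$a) || prev_wcss - wcss < tol) {
      converged <- identical(new_asg$a, asg$a)
      asg <- new_asg
      break
    }
    asg <- new_asg
    prev_wcss <- wcss
    if (iter >= max_iter) break
  }
  list(assignments = asg$a, centroids = centers, wcss = sum(asg$d),
       iterations = iter, converged = converged)
}

#' Contingency table of true classes x clusters
#' @param truth_labels true class per point.
#' @param cluster_labels cluster id per point.
#' @return a `table` (classes in rows, clusters in columns).
#' @export
contingency <- function(truth_labels, cluster_labels) {
  if (length(truth_labels) != length(cluster_labels)) {
    stop("label vectors differ in length")
  }
  table(class = truth_labels, cluster = cluster_labels)
}

#' Homogeneity of a clustering against true classes
#'
#' homogeneity = 1 - E(A|C) / E(A), where E(A) is the entropy of the true
#' class distribution and E(A|C) the conditional entropy of classes given
#' clusters, E(A|C) = -sum_mk (n_mk / N) * log(n_mk / c_k) with c_k the
#' cluster size (`mode = "conditional"`, the default: 1 for a perfect
#' clustering, 0 when a single cluster holds balanced classes). The
#' printed variant with the class-size denominator a_m is available as
#' `mode = "printed"` for comparison; it does not behave as a
#' homogeneity measure in the degenerate one-cluster case. Natural
#' logarithms; the base cancels in the ratio. Conventions: 0*log(.) = 0;
#' if E(A) = 0 (a single true class) the score is 1.
#'
#' @param truth_labels true class per point.
#' @param cluster_labels cluster id per point.
#' @param mode `"conditional"` (default) or `"printed"`.
#' @return scalar in [0, 1] (the printed mode can leave the interval).
#' @export
homogeneity_score <- function(truth_labels, cluster_labels,
                              mode = c("conditional", "printed")) {
  mode <- match.arg(mode)
  tab <- contingency(truth_labels, cluster_labels)
  N <- sum(tab)
  a_m <- rowSums(tab)
  c_k <- colSums(tab)
  ea <- -sum(ifelse(a_m > 0, (a_m / N) * log(a_m / N), 0))
  if (ea == 0) return(1)
  denom <- if (mode == "conditional") {
    matrix(c_k, nrow(tab), ncol(tab), byrow = TRUE)
  } else {
    matrix(a_m, nrow(tab), ncol(tab))
  }
  terms <- ifelse(tab > 0, (tab / N) * log(tab / denom), 0)
  eac <- -sum(terms)
  1 - eac / ea
}

#' Per-cluster purity
#'
#' For each non-empty cluster, the fraction of its members belonging to
#' its majority true class.
#'
#' @inheritParams homogeneity_score
#' @return named numeric vector, one entry per cluster id present.
#' @export
per_cluster_purity <- function(truth_labels, cluster_labels) {
  tab <- contingency(truth_labels, cluster_labels)
  apply(tab, 2L, function(col) max(col) / sum(col))
}

#' Homogeneity-constrained selection of the number of clusters
#'
#' Runs k-means for every k in `k_range`; among the values of k whose
#' minimum per-cluster purity exceeds `purity_threshold`, returns the
#' clustering maximizing the global homogeneity score, ties broken toward
#' the smallest k. If no k satisfies the constraint the best-homogeneity
#' clustering is returned with `constraint_met = FALSE`.
#'
#' @param X numeric matrix (points x dims).
#' @param truth_labels known identity per point (the evaluation oracle the
#'   constraint is computed against).
#' @param k_range candidate cluster counts, default 2:15.
#' @param purity_threshold strict per-cluster purity constraint, default 0.95.
#' @param seed integer seed.
#' @param n_init restarts per k.
#' @return a `cluster_result` augmented with `homogeneity`,
#'   `per_cluster_purity`, `min_purity`, `constraint_met`, and
#'   `evaluated` (per-k summary data.frame).
#' @export
select_k <- function(X, truth_labels, k_range = 2:15, purity_threshold = 0.95,
                     seed = 1L, n_init = 10L) {
  if (length(k_range) == 0L) stop("empty k_range")
  fits <- list()
  evals <- list()
  for (k in k_range) {
    fit <- kmeans_lloyd(X, k, seed = substream_seed(seed, "select_k", k),
                        n_init = n_init)
    pur <- per_cluster_purity(truth_labels, fit$assignments)
    hom <- homogeneity_score(truth_labels, fit$assignments)
    fits[[as.character(k)]] <- fit
    evals[[as.character(k)]] <- data.frame(
      k = k, wcss = fit$wcss, homogeneity = hom, min_purity = min(pur))
  }
  ev <- do.call(rbind, evals)
  ok <- ev$min_purity > purity_threshold
  pick <- if (any(ok)) {
    cand <- ev[ok, ]
    cand$k[which.max(cand$homogeneity)]  # which.max -> first max -> smallest k
  } else {
    ev$k[which.max(ev$homogeneity)]
  }
  fit <- fits[[as.character(pick)]]
  fit$homogeneity <- ev$homogeneity[ev$k == pick]
  fit$per_cluster_purity <- per_cluster_purity(truth_labels, fit$assignments)
  fit$min_purity <- min(fit$per_cluster_purity)
  fit$constraint_met <- any(ok)
  fit$evaluated <- ev
  fit
}

#' Cluster a feature table in the standardized principal-component space
#'
#' Convenience wrapper for the sub-phenotype analysis: collapses the table
#' to per-cell mean vectors (or keeps rows with `per_cell = FALSE`),
#' z-scores, projects to `n_components` principal components, and runs
#' [select_k()] against the supplied per-cell truth labels.
#'
#' @param table feature table (manifest schema).
#' @param labels data.frame `cell_id` plus the truth column named by
#'   `truth_col` (default `"subphenotype_id"`).
#' @param truth_col name of the truth column in `labels`.
#' @param n_components principal components, default 14.
#' @param per_cell cluster per-cell mean vectors (default) or rows.
#' @inheritParams select_k
#' @return as [select_k()], plus `cell_id` order used.
#' @export
cluster_subphenotypes <- function(table, labels, truth_col = "subphenotype_id",
                                  n_components = 14L, per_cell = TRUE,
                                  k_range = 2:15, purity_threshold = 0.95,
                                  seed = 1L, n_init = 10L) {
  man <- feature_manifest()$name
  if (per_cell) {
    agg <- aggregate_cells(table)
    X <- as.matrix(agg[man]); ids <- agg$cell_id
  } else {
    X <- as.matrix(table[man]); ids <- table$cell_id
  }
  truth <- stats::setNames(labels[[truth_col]], labels$cell_id)[ids]
  if (anyNA(truth)) stop("truth labels missing for some cells")
  pp <- fit_preprocessor(X, n_components)
  P <- preproc_transform(pp, X)
  res <- select_k(P, truth, k_range = k_range,
                  purity_threshold = purity_threshold,
                  seed = seed, n_init = n_init)
  res$cell_id <- ids
  res
}
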