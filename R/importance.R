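#' Random-forest permutation-importance ranks
#'
#' Fits a random forest and ranks features by permutation importance (mean
#' decrease in out-of-bag accuracy when a feature's values are permuted);
#' the largest decrease receives rank 1. Ties are broken by feature order.
#'
#' @param x,y training features and binary labels.
#' @param num_trees,mtry forest parameters (defaults 500 and `floor(sqrt(p))`).
#' @param seed optional integer seed.
#' @return named integer vector of ranks, a permutation of `1..ncol(x)`.
#' @export
rf_importance_ranks <- function(x, y, num_trees = 500, mtry = NULL, seed = NULL) {
  y <- as_binary_labels(y)
  with_seed(seed, {
    d <- data.frame(.y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = d,
      num.trees = num_trees,
      mtry = mtry %||% max(1L, floor(sqrt(ncol(x)))),
      importance = "permutation", num.threads = 1L, seed = draw_seed()
    )
    imp <- fit$variable.importance[colnames(x)]
    ranks <- as.integer(rank(-imp, ties.method = "first"))
    names(ranks) <- colnames(x)
    ranks
  })
}

# Cross-validated accuracy of one classifier on a feature subset.
cv_accuracy <- function(kind, params, x, y, n_folds = 5, seed = NULL) {
  fold <- make_folds(y, n_folds, stratified = TRUE, seed = seed)
  lab <- integer(length(y))
  for (f in seq_len(max(fold))) {
    te <- fold == f
    lab[te] <- fit_predict(kind, params, x[!te, , drop = FALSE], y[!te],
                           x[te, , drop = FALSE])$label
  }
  mean(lab == y)
}

#' SVM recursive-feature-elimination ranks
#'
#' Backward elimination driven by classification performance: at each step
#' the feature whose removal least degrades the cross-validated accuracy of
#' the RBF SVM is eliminated; the elimination order reversed gives the ranks
#' (the last surviving feature has rank 1). Ties (equal accuracy) are broken
#' by feature order.
#'
#' @param x,y training features and binary labels.
#' @param cost,gamma SVM parameters (defaults 1 and `1/ncol(x)`).
#' @param n_folds folds for the accuracy estimates (default 5).
#' @param seed optional integer seed (fold splits are re-drawn per step from
#'   this stream).
#' @return named integer vector of ranks, a permutation of `1..ncol(x)`.
#' @export
svm_rfe_ranks <- function(x, y, cost = 1, gamma = NULL, n_folds = 5, seed = NULL) {
  p <- ncol(x)
  if (p < 2L) stop("recursive elimination needs at least 2 features")
  y <- as_binary_labels(y)
  params <- list(cost = cost, gamma = gamma %||% (1 / p))
  with_seed(seed, {
    remaining <- seq_len(p)
    eliminated <- integer(0)
    while (length(remaining) > 1L) {
      fold_seed <- draw_seed()
      acc <- vapply(seq_along(remaining), function(j) {
        keep <- remaining[-j]
        cv_accuracy("svm_rbf", params, x[, keep, drop = FALSE], y,
                    n_folds = n_folds, seed = fold_seed)
      }, numeric(1))
      worst <- remaining[which.max(acc)] # removal hurts least
      eliminated <- c(eliminated, worst)
      remaining <- setdiff(remaining, worst)
    }
    order_removed <- c(eliminated, remaining) # first removed ... survivor
    ranks <- integer(p)
    ranks[order_removed] <- p:1
    names(ranks) <- colnames(x)
    ranks
  })
}

#' KNN leave-one-feature-out importance ranks
#'
#' Ranks features by the degradation of cross-validated KNN accuracy when
#' the feature is left out (largest degradation = rank 1). This is a simple,
#' testable feature-support criterion for KNN; ties are broken by feature
#' order.
#'
#' @param x,y training features and binary labels.
#' @param k neighbour count (default 5).
#' @param n_folds folds for the accuracy estimates (default 5).
#' @param seed optional integer seed.
#' @return named integer vector of ranks, a permutation of `1..ncol(x)`.
#' @export
knn_lofo_ranks <- function(x, y, k = 5, n_folds = 5, seed = NULL) {
  p <- ncol(x)
  if (p < 2L) stop("leave-one-feature-out needs at least 2 features")
  y <- as_binary_labels(y)
  with_seed(seed, {
    fold_seed <- draw_seed()
    acc <- vapply(seq_len(p), function(j) {
      cv_accuracy("knn", list(k = k), x[, -j, drop = FALSE], y,
                  n_folds = n_folds, seed = fold_seed)
    }, numeric(1))
    # lower accuracy without the feature => more important
    ranks <- as.integer(rank(acc, ties.method = "first"))
    names(ranks) <- colnames(x)
    ranks
  })
}

#' Aggregate per-classifier importance ranks into the ensemble voting rank
#'
#' The ensemble importance of a feature is the mean of its three
#' per-classifier ranks; features are ordered by ascending mean rank. Ties
#' are broken first by the best (minimum) single-classifier rank, then by
#' feature label order.
#'
#' @param ranks a data frame with columns `feature`, `rank_knn`, `rank_rf`,
#'   `rank_svm` (integer ranks, 1 = most important; the columns may come
#'   from different-sized rankings, e.g. a published top-20 slice).
#' @return data frame of class `"importance_table"`, ordered by
#'   `voting_rank`, with added columns `mean_rank` and `voting_rank`.
#' @examples
#' r <- data.frame(feature = c("A", "B", "C"),
#'                 rank_knn = c(2, 1, 3), rank_rf = c(1, 3, 2),
#'                 rank_svm = c(2, 3, 1))
#' average_ranks(r)
#' @export
average_ranks <- function(ranks) {
  req <- c("feature", "rank_knn", "rank_rf", "rank_svm")
  if (!all(req %in% names(ranks))) {
    stop("need columns: ", paste(req, collapse = ", "))
  }
  rk <- ranks[, c("rank_knn", "rank_rf", "rank_svm")]
  if (anyNA(rk)) stop("missing rank entries")
  ranks$mean_rank <- rowMeans(rk)
  best <- do.call(pmin, rk)
  ord <- order(ranks$mean_rank, best, ranks$feature)
  out <- ranks[ord, , drop = FALSE]
  out$voting_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Ensemble variable importance for a training set
#'
#' Computes the three per-classifier rankings ([rf_importance_ranks()],
#' [svm_rfe_ranks()], [knn_lofo_ranks()]) on the supplied (typically
#' rebalanced) training set and aggregates them with [average_ranks()].
#'
#' @param x,y training features and binary labels.
#' @param seed optional integer seed shared by the three rankers.
#' @param ... passed on to the individual rankers.
#' @return an `"importance_table"` data frame.
#' @export
ensemble_importance <- function(x, y, seed = NULL, ...) {
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  r_rf <- rf_importance_ranks(x, y, seed = seed)
  r_svm <- svm_rfe_ranks(x, y, seed = if (is.null(seed)) NULL else seed + 1L)
  r_knn <- knn_lofo_ranks(x, y, seed = if (is.null(seed)) NULL else seed + 2L)
  average_ranks(data.frame(
    feature = colnames(x),
    rank_knn = unname(r_knn),
    rank_rf = unname(r_rf),
    rank_svm = unname(r_svm),
    stringsAsFactors = FALSE
  ))
}

#' @export
print.importance_table <- function(x, n = 20, ...) {
  cat("Ensemble variable importance (rank-averaged), top", min(n, nrow(x)), "of",
      nrow(x), "features:\n")
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE, ...)
  invisible(x)
}

#' Top-k importance overlap between classifiers
#'
#' Lists the features appearing in the top `k` of all three per-classifier
#' rankings, and those unique to each (a plain-text Venn-style summary).
#'
#' @param tab an `"importance_table"` data frame.
#' @param k cutoff (default 20).
#' @return list with `shared_all` and per-classifier `unique_*` character
#'   vectors.
#' @export
importance_overlap <- function(tab, k = 20) {
  top <- lapply(c(knn = "rank_knn", rf = "rank_rf", svm = "rank_svm"),
                function(cl) tab$feature[tab[[cl]] <= k])
  list(
    shared_all = Reduce(intersect, top),
    unique_knn = setdiff(top$knn, union(top$rf, top$svm)),
    unique_rf = setdiff(top$rf, union(top$knn, top$svm)),
    unique_svm = setdiff(top$svm, union(top$knn, top$rf))
  )
}
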