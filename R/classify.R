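#' Cross-validation control parameters
#'
#' @param n_folds number of CV folds (default 10).
#' @param n_repeats number of CV repetitions (default 50; the full-scale
#'   analysis uses 1000).
#' @param stratified preserve the class ratio within folds (default TRUE).
#' @param base_seed integer; repeat `r` uses seed `base_seed + r`, so repeats
#'   are independent but the whole run is reproducible.
#' @return a list of class `"cv_control"`.
#' @export
cv_control <- function(n_folds = 10, n_repeats = 50, stratified = TRUE,
                       base_seed = 1L) {
  if (n_folds < 2) stop("'n_folds' must be at least 2")
  if (n_repeats < 1) stop("'n_repeats' must be positive")
  structure(
    list(
      n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
      stratified = isTRUE(stratified), base_seed = as.integer(base_seed)
    ),
    class = "cv_control"
  )
}

#' Default hyperparameter grids for the three base classifiers
#'
#' Compact grids centred on the standard defaults: random forest at the
#' canonical `mtry = floor(sqrt(p))` with 500 trees; RBF-kernel SVM over
#' cost and kernel width; KNN over odd `k` (odd values avoid vote ties).
#' Each grid is a data frame whose rows are candidate configurations; grids
#' are fully configurable and a single-row grid skips inner tuning.
#'
#' @param p number of features.
#' @return named list of data frames for `random_forest`, `svm_rbf`, `knn`.
#' @export
default_grids <- function(p) {
  list(
    random_forest = data.frame(mtry = max(1L, floor(sqrt(p))), num_trees = 500L),
    svm_rbf = expand.grid(cost = c(1, 10, 100), gamma = c(1, 2) / p),
    knn = data.frame(k = c(3L, 5L, 7L, 9L, 11L, 15L))
  )
}

#' Partition samples into cross-validation folds
#'
#' Stratified folds distribute each class across folds round-robin after a
#' random shuffle, so the within-fold class ratio matches the overall ratio
#' to within one sample.
#'
#' @param y binary labels.
#' @param n_folds number of folds.
#' @param stratified logical.
#' @param seed optional integer seed.
#' @return integer vector of fold ids (1..n_folds), one per sample.
#' @export
make_folds <- function(y, n_folds = 10, stratified = TRUE, seed = NULL) {
  y <- as_binary_labels(y)
  n <- length(y)
  if (n < n_folds) stop("fewer samples than folds")
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        if (length(idx) < n_folds) {
          stop(sprintf(
            "class %d has %d samples, fewer than n_folds = %d; cannot stratify",
            cls, length(idx), n_folds
          ))
        }
        fold[sample(idx)] <- rep(seq_len(n_folds), length.out = length(idx))
      }
    } else {
      fold <- sample(rep(seq_len(n_folds), length.out = n))
    }
    fold
  })
}

#' Fit one classifier and predict held-out samples
#'
#' Score semantics: random forest returns the fraction of trees voting for
#' the positive class; KNN the fraction of the k nearest training neighbours
#' that are positive; the SVM score is a monotone (logistic) transform of
#' the signed decision value, oriented so larger means more positive (AUC is
#' invariant to the monotone transform). For random forest and KNN the
#' predicted label is `score >= 0.5`; the SVM label is its own class
#' prediction.
#'
#' @param kind `"random_forest"`, `"svm_rbf"` or `"knn"`.
#' @param params a one-row data frame (or list) of hyperparameters, see
#'   [default_grids()].
#' @param x_train,y_train training features and binary labels.
#' @param x_test held-out features (same columns as `x_train`).
#' @return list with `label` (integer 0/1) and `score` (numeric in `[0, 1]`)
#'   per test row.
#' @export
fit_predict <- function(kind, params, x_train, y_train, x_test) {
  y_train <- as_binary_labels(y_train)
  if (ncol(x_test) != ncol(x_train)) stop("test feature count mismatch")
  if (length(unique(y_train)) < 2L) stop("training data must contain both classes")
  params <- as.list(params)
  switch(kind,
    random_forest = {
      d <- data.frame(.y = factor(y_train, levels = c(0, 1)), x_train,
                      check.names = FALSE)
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = d,
        num.trees = params$num_trees %||% 500L,
        mtry = params$mtry %||% max(1L, floor(sqrt(ncol(x_train)))),
        probability = TRUE, num.threads = 1L, seed = draw_seed()
      )
      score <- stats::predict(fit,
        data.frame(x_test, check.names = FALSE),
        num.threads = 1L
      )$predictions[, "1"]
      list(label = as.integer(score >= 0.5), score = unname(score))
    },
    svm_rbf = {
      fit <- e1071::svm(x_train, factor(y_train, levels = c(0, 1)),
        kernel = "radial",
        cost = params$cost %||% 1,
        gamma = params$gamma %||% (1 / ncol(x_train)),
        scale = FALSE
      )
      pred <- stats::predict(fit, x_test, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # decision values are signed towards the first class named in the
      # "a/b" column label; flip so larger always means class 1
      dv_name <- colnames(attr(pred, "decision.values"))[1]
      if (identical(dv_name, "0/1")) dv <- -dv
      list(label = as.integer(as.character(pred)), score = stats::plogis(dv))
    },
    knn = {
      k <- params$k %||% 5L
      pred <- class::knn(x_train, x_test, factor(y_train, levels = c(0, 1)),
                         k = k, prob = TRUE)
      pwin <- attr(pred, "prob")
      score <- ifelse(pred == "1", pwin, 1 - pwin)
      list(label = as.integer(score >= 0.5), score = unname(score))
    },
    stop("unknown classifier kind: ", kind)
  )
}

#' Grid-search hyperparameter tuning by inner cross-validation
#'
#' Selects the grid row maximizing accuracy (or AUC) estimated by an inner
#' stratified cross-validation on the supplied training partition only.
#' Ties are broken by grid order; a single-row grid is returned immediately
#' without inner CV.
#'
#' @param kind classifier kind (see [fit_predict()]).
#' @param grid data frame of candidate hyperparameter rows.
#' @param x,y training partition features and labels.
#' @param inner_folds number of inner folds (default 5).
#' @param metric `"accuracy"` (default) or `"auc"`.
#' @param seed optional integer seed for the inner fold split.
#' @return the chosen one-row data frame of hyperparameters.
#' @export
tune_classifier <- function(kind, grid, x, y, inner_folds = 5,
                            metric = c("accuracy", "auc"), seed = NULL) {
  metric <- match.arg(metric)
  if (!nrow(grid)) stop("empty tuning grid")
  if (nrow(grid) == 1L) return(grid)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("cannot tune on a single-class partition")
  inner_folds <- min(inner_folds, min(table(y)))
  fold <- make_folds(y, inner_folds, stratified = TRUE, seed = seed)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    lab <- integer(length(y)); sc <- numeric(length(y))
    for (f in seq_len(inner_folds)) {
      te <- fold == f
      pr <- fit_predict(kind, grid[g, , drop = FALSE],
                        x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
      lab[te] <- pr$label; sc[te] <- pr$score
    }
    if (metric == "accuracy") mean(lab == y) else auc_rank(sc, y)
  }, numeric(1))
  grid[which.max(scores), , drop = FALSE]
}
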