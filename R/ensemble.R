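#' Majority vote over three binary classifiers
#'
#' Each sample receives the label predicted by at least two of the three
#' classifiers; with three binary voters no ties are possible.
#'
#' @param labels_rf,labels_svm,labels_knn equal-length binary label vectors.
#' @return integer 0/1 vector of voted labels.
#' @export
majority_vote <- function(labels_rf, labels_svm, labels_knn) {
  if (length(labels_rf) != length(labels_svm) ||
      length(labels_svm) != length(labels_knn)) {
    stop("vote vectors must have equal length")
  }
  votes <- as_binary_labels(labels_rf) + as_binary_labels(labels_svm) +
    as_binary_labels(labels_knn)
  as.integer(votes >= 2L)
}

#' Continuous ensemble score for the voting classifier
#'
#' The default ensemble score is the arithmetic mean of the three base
#' classifiers' positive-class scores; the `"vote_fraction"` mode instead
#' returns the fraction of positive votes (0, 1/3, 2/3 or 1) from the hard
#' labels.
#'
#' @param score_rf,score_svm,score_knn base scores in `[0, 1]` (or hard 0/1
#'   labels in `"vote_fraction"` mode).
#' @param mode `"mean"` (default) or `"vote_fraction"`.
#' @return numeric vector in `[0, 1]`.
#' @export
voting_score <- function(score_rf, score_svm, score_knn,
                         mode = c("mean", "vote_fraction")) {
  mode <- match.arg(mode)
  s <- cbind(score_rf, score_svm, score_knn)
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("scores must lie in [0, 1]")
  if (mode == "vote_fraction") {
    rowSums(s >= 0.5) / 3
  } else {
    rowMeans(s)
  }
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' AUC = P(score of a random positive > score of a random negative)
#' + 0.5 P(equal), computed from midranks.
#'
#' @param scores numeric scores.
#' @param truth binary truth labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, truth) {
  truth <- as_binary_labels(truth)
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: truth labels contain a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics plus AUC for one set of predictions
#'
#' @param labels predicted binary labels.
#' @param scores continuous positive-class scores.
#' @param truth true binary labels (must contain both classes).
#' @return named numeric vector: `accuracy`, `sensitivity`, `specificity`,
#'   `auc`.
#' @export
compute_metrics <- function(labels, scores, truth) {
  truth <- as_binary_labels(truth)
  labels <- as_binary_labels(labels)
  if (length(unique(truth)) < 2L) {
    stop("metrics undefined: truth labels contain a single class")
  }
  tp <- sum(labels == 1L & truth == 1L)
  tn <- sum(labels == 0L & truth == 0L)
  fp <- sum(labels == 1L & truth == 0L)
  fn <- sum(labels == 0L & truth == 1L)
  c(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = auc_rank(scores, truth)
  )
}

classifier_kinds <- c("random_forest", "svm_rbf", "knn")
method_names <- c("random_forest", "svm_rbf", "knn", "voting")

# One repeat of k-fold CV on (x, y): returns pooled held-out labels/scores
# per classifier plus the evaluation truth. Tuning is nested: the grid is
# re-tuned by inner CV within every training partition. In within_fold
# resampling mode each training partition is rebalanced before tuning and
# fitting; held-out samples are never resampled.
cv_one_repeat <- function(x, y, grids, cv, resample = NULL, tune = TRUE) {
  fold <- make_folds(y, cv$n_folds, cv$stratified)
  n <- length(y)
  lab <- matrix(NA_integer_, n, 3L, dimnames = list(NULL, classifier_kinds))
  sc <- matrix(NA_real_, n, 3L, dimnames = list(NULL, classifier_kinds))
  for (f in seq_len(cv$n_folds)) {
    te <- fold == f
    x_tr <- x[!te, , drop = FALSE]; y_tr <- y[!te]
    if (!is.null(resample) && resample$mode == "within_fold") {
      rs <- rebalance(x_tr, y_tr, resample, seed = NULL)
      x_tr <- rs$x; y_tr <- rs$y
    }
    for (kind in classifier_kinds) {
      params <- if (tune) {
        tune_classifier(kind, grids[[kind]], x_tr, y_tr)
      } else {
        grids[[kind]][1L, , drop = FALSE]
      }
      pr <- fit_predict(kind, params, x_tr, y_tr, x[te, , drop = FALSE])
      lab[te, kind] <- pr$label
      sc[te, kind] <- pr$score
    }
  }
  list(labels = lab, scores = sc, truth = y)
}

#' Fit and evaluate the majority-voting BV prediction ensemble
#'
#' The core modelling function. Given a preprocessed feature matrix and
#' binary incident-BV labels it (optionally) rebalances the training set
#' with SMOTE + undersampling, evaluates random forest, RBF-SVM and KNN
#' classifiers and their majority-voting ensemble under repeated stratified
#' k-fold cross-validation with nested grid-search tuning, and fits final
#' models on the full (rebalanced) training set for use by
#' [predict.bv_ensemble()].
#'
#' Per repeat, held-out predictions are pooled across folds and scored
#' (accuracy, sensitivity, specificity, rank AUC); reported point values are
#' means over repeats, and the per-repeat AUC distributions are retained for
#' [permutation_t_test()].
#'
#' @param x samples x features numeric matrix (see [assemble_features()]).
#' @param y binary labels, 1 = incident BV.
#' @param cv a [cv_control()] object.
#' @param resample a [resample_control()] object, or `NULL` for no
#'   rebalancing. In the default `"pre_cv"` mode the full set is rebalanced
#'   once before cross-validation (faithful to the original analysis design;
#'   synthetic points then appear in held-out folds). `"within_fold"`
#'   rebalances training folds only.
#' @param grids named list of tuning grids (default [default_grids()]).
#' @param tune logical; nested inner-CV tuning per training partition
#'   (default TRUE). With `FALSE`, the first row of each grid is used.
#' @param voting_mode ensemble score construction, see [voting_score()].
#' @param fit_final fit full-training-set models for [predict.bv_ensemble()]
#'   (default TRUE).
#' @return an object of class `"bv_ensemble"` with components
#'   `performance` (4 metrics x 4 methods matrix of means over repeats),
#'   `auc_distribution` (n_repeats x 4 matrix), `training` (the evaluated
#'   training set incl. provenance), `final_models`, and the configuration.
#' @examples
#' sim <- simulate_cohort(60, n_taxa = 15, effect_taxa = 1:3, seed = 1)
#' ch <- build_cohort(sim$metadata, sim$counts)
#' fe <- assemble_features(ch, seed = 1)
#' fit <- bv_ensemble(fe$x, fe$y, cv = cv_control(n_folds = 5, n_repeats = 2),
#'                    tune = FALSE, fit_final = FALSE)
#' fit$performance
#' @export
bv_ensemble <- function(x, y,
                        cv = cv_control(),
                        resample = resample_control(),
                        grids = NULL,
                        tune = TRUE,
                        voting_mode = c("mean", "vote_fraction"),
                        fit_final = TRUE) {
  voting_mode <- match.arg(voting_mode)
  y <- as_binary_labels(y)
  if (!is.matrix(x) || nrow(x) != length(y)) stop("'x' rows must match 'y' length")
  cl <- match.call()

  provenance <- rep("original", length(y))
  if (!is.null(resample) && resample$mode == "pre_cv") {
    rs <- rebalance(x, y, resample, seed = resample$seed %||% cv$base_seed)
    x_eval <- rs$x; y_eval <- rs$y; provenance <- rs$provenance
  } else {
    x_eval <- x; y_eval <- y
  }
  if (is.null(grids)) grids <- default_grids(ncol(x_eval))

  n_rep <- cv$n_repeats
  metric_names <- c("accuracy", "sensitivity", "specificity", "auc")
  per_repeat <- array(NA_real_, c(n_rep, 4L, 4L),
                      dimnames = list(NULL, metric_names, method_names))
  auc_dist <- matrix(NA_real_, n_rep, 4L, dimnames = list(NULL, method_names))

  for (r in seq_len(n_rep)) {
    rep_res <- with_seed(cv$base_seed + r, {
      cv_one_repeat(x_eval, y_eval, grids, cv,
        resample = if (!is.null(resample) && resample$mode == "within_fold") resample,
        tune = tune
      )
    })
    v_lab <- majority_vote(
      rep_res$labels[, "random_forest"], rep_res$labels[, "svm_rbf"],
      rep_res$labels[, "knn"]
    )
    v_sc <- if (voting_mode == "vote_fraction") {
      voting_score(rep_res$labels[, "random_forest"], rep_res$labels[, "svm_rbf"],
                   rep_res$labels[, "knn"], mode = "vote_fraction")
    } else {
      voting_score(rep_res$scores[, "random_forest"], rep_res$scores[, "svm_rbf"],
                   rep_res$scores[, "knn"])
    }
    for (kind in classifier_kinds) {
      per_repeat[r, , kind] <- compute_metrics(
        rep_res$labels[, kind], rep_res$scores[, kind], rep_res$truth
      )
    }
    per_repeat[r, , "voting"] <- compute_metrics(v_lab, v_sc, rep_res$truth)
    auc_dist[r, ] <- per_repeat[r, "auc", ]
  }

  performance <- apply(per_repeat, c(2L, 3L), mean)

  final_models <- NULL
  if (fit_final) {
    final_models <- with_seed(cv$base_seed, {
      lapply(stats::setNames(classifier_kinds, classifier_kinds), function(kind) {
        params <- if (tune) {
          tune_classifier(kind, grids[[kind]], x_eval, y_eval)
        } else {
          grids[[kind]][1L, , drop = FALSE]
        }
        list(kind = kind, params = params)
      })
    })
  }

  structure(
    list(
      call = cl,
      performance = performance,
      auc_distribution = auc_dist,
      per_repeat = per_repeat,
      training = list(x = x_eval, y = y_eval, provenance = provenance),
      final_models = final_models,
      cv = cv, resample = resample, grids = grids, tune = tune,
      voting_mode = voting_mode
    ),
    class = "bv_ensemble"
  )
}

#' @export
print.bv_ensemble <- function(x, digits = 3, ...) {
  cat("Majority-voting BV prediction ensemble (RF + RBF-SVM + KNN)\n")
  cat(sprintf(
    "  training set: %d samples (%d synthetic), %d features\n",
    nrow(x$training$x), sum(x$training$provenance == "synthetic"),
    ncol(x$training$x)
  ))
  cat(sprintf(
    "  evaluation: %d-fold CV repeated %d times%s\n",
    x$cv$n_folds, x$cv$n_repeats,
    if (x$tune) ", nested grid-search tuning" else ""
  ))
  cat("\nMean held-out performance over repeats:\n")
  print(round(x$performance, digits))
  invisible(x)
}

#' @export
summary.bv_ensemble <- function(object, ...) {
  out <- list(
    performance = object$performance,
    auc_quantiles = apply(object$auc_distribution, 2L, stats::quantile,
                          probs = c(0.025, 0.25, 0.5, 0.75, 0.975)),
    n_repeats = object$cv$n_repeats
  )
  class(out) <- "summary.bv_ensemble"
  out
}

#' @export
print.summary.bv_ensemble <- function(x, digits = 3, ...) {
  cat("Mean held-out performance over", x$n_repeats, "repeats:\n")
  print(round(x$performance, digits))
  cat("\nPer-repeat AUC distribution quantiles:\n")
  print(round(x$auc_quantiles, digits))
  invisible(x)
}

#' Plot per-repeat AUC distributions
#'
#' Box plots of the held-out AUC per cross-validation repeat, one box per
#' classifier plus the voting ensemble.
#'
#' @param x a `"bv_ensemble"` fit.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.bv_ensemble <- function(x, ...) {
  graphics::boxplot(x$auc_distribution,
    ylab = "held-out AUC per repeat",
    names = c("RF", "SVM", "KNN", "Voting"), ...
  )
  invisible(x)
}

#' Predict incident-BV class for new samples
#'
#' Applies the final models (fitted on the full rebalanced training set) and
#' combines them by majority vote; `type = "score"` returns the continuous
#' ensemble score alongside the base classifiers'.
#'
#' @param object a `"bv_ensemble"` fit with `fit_final = TRUE`.
#' @param newdata samples x features matrix on the training feature scale.
#' @param type `"class"` (default) for voted 0/1 labels, `"score"` for a
#'   matrix of base and ensemble scores.
#' @param ... unused.
#' @export
predict.bv_ensemble <- function(object, newdata,
                                type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(object$final_models)) {
    stop("fit was created with fit_final = FALSE; refit to enable prediction")
  }
  preds <- lapply(object$final_models, function(m) {
    fit_predict(m$kind, m$params, object$training$x, object$training$y, newdata)
  })
  if (type == "class") {
    majority_vote(
      preds$random_forest$label, preds$svm_rbf$label, preds$knn$label
    )
  } else {
    s <- cbind(
      random_forest = preds$random_forest$score,
      svm_rbf = preds$svm_rbf$score,
      knn = preds$knn$score
    )
    cbind(s, voting = voting_score(s[, 1], s[, 2], s[, 3],
                                   mode = object$voting_mode))
  }
}
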