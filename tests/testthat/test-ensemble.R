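test_that("majority vote matches enumeration of all 8 vote patterns", {
  patterns <- expand.grid(rf = 0:1, svm = 0:1, knn = 0:1)
  expected <- as.integer(rowSums(patterns) >= 2)
  got <- majority_vote(patterns$rf, patterns$svm, patterns$knn)
  expect_equal(got, expected)
  expect_error(majority_vote(c(0, 1), c(0, 1, 1), c(1, 1)), "equal length")
})

test_that("voting score is the mean (or the vote fraction)", {
  expect_equal(voting_score(0.9, 0.6, 0.3), 0.6)
  s <- runif(5)
  expect_equal(voting_score(s, s, s), s)
  expect_equal(voting_score(1, 1, 0, mode = "vote_fraction"), 2 / 3)
  expect_error(voting_score(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("confusion metrics and AUC match hand arithmetic", {
  # TP=3, FN=1, TN=4, FP=2
  truth <- c(rep(1, 4), rep(0, 6))
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  scores <- ifelse(labels == 1, 0.9, 0.1)
  m <- compute_metrics(labels, scores, truth)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m["accuracy"]), 0.7)

  # perfect separation and the all-tie case
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_rank(runif(4), rep(1, 4)), "single class")
  expect_error(compute_metrics(c(0, 1), c(0.2, 0.8), c(1, 1)), "single class")
})

test_that("rank AUC agrees with brute-force pairwise comparison and pROC", {
  set.seed(14)
  for (i in 1:5) {
    truth <- rbinom(25, 1, 0.4)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(25), 1)  # coarse grid forces ties
    expect_equal(auc_rank(scores, truth), auc_brute(scores, truth))
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    truth <- rbinom(40, 1, 0.5)
    scores <- runif(40)
    expect_equal(
      auc_rank(scores, truth),
      as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    )
  }
})

test_that("ensemble evaluation pools folds per repeat and keeps AUC vectors", {
  cl <- make_two_clusters(60, sep = 3, seed = 15)
  fit <- bv_ensemble(cl$x, cl$y, cv = cv_control(5, 3, base_seed = 20),
                     resample = NULL, tune = FALSE, fit_final = FALSE)
  expect_equal(dim(fit$auc_distribution), c(3L, 4L))
  expect_true(all(fit$auc_distribution >= 0 & fit$auc_distribution <= 1))
  expect_equal(colnames(fit$performance),
               c("random_forest", "svm_rbf", "knn", "voting"))

  # with one repeat, the summary equals the single repeat's metrics
  fit1 <- bv_ensemble(cl$x, cl$y, cv = cv_control(5, 1, base_seed = 20),
                      resample = NULL, tune = FALSE, fit_final = FALSE)
  expect_equal(fit1$performance, fit1$per_repeat[1, , ])

  # identical configuration twice -> identical numeric results
  fit1b <- bv_ensemble(cl$x, cl$y, cv = cv_control(5, 1, base_seed = 20),
                       resample = NULL, tune = FALSE, fit_final = FALSE)
  expect_identical(fit1$performance, fit1b$performance)

  # voting sensitivity/specificity lie between the classifiers' per repeat
  for (r in 1:3) {
    for (metric in c("sensitivity", "specificity")) {
      vals <- fit$per_repeat[r, metric, c("random_forest", "svm_rbf", "knn")]
      v <- fit$per_repeat[r, metric, "voting"]
      expect_gte(v, min(vals) - 1e-12)
      expect_lte(v, max(vals) + 1e-12)
    }
  }
})

test_that("metrics are invariant to sample ordering", {
  set.seed(16)
  truth <- rbinom(30, 1, 0.5)
  labels <- rbinom(30, 1, 0.5)
  scores <- runif(30)
  perm <- sample(30)
  expect_equal(compute_metrics(labels, scores, truth),
               compute_metrics(labels[perm], scores[perm], truth[perm]))
})

test_that("prediction methods work on new samples", {
  cl <- make_two_clusters(80, sep = 5, seed = 17)
  fit <- bv_ensemble(cl$x, cl$y, cv = cv_control(5, 1, base_seed = 3),
                     resample = NULL, tune = FALSE, fit_final = TRUE)
  new <- make_two_clusters(20, sep = 5, seed = 18)
  lab <- predict(fit, new$x)
  expect_gte(mean(lab == new$y), 0.9)
  sc <- predict(fit, new$x, type = "score")
  expect_equal(colnames(sc), c("random_forest", "svm_rbf", "knn", "voting"))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_output(print(fit), "Majority-voting")
  expect_output(print(summary(fit)), "quantiles")
})
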