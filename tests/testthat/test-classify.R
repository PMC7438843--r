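test_that("fold construction partitions samples with stratification", {
  y <- rep(c(0, 1), each = 10)
  f <- make_folds(y, 10, stratified = FALSE, seed = 1)
  expect_equal(as.integer(table(f)), rep(2L, 10))

  fs <- make_folds(y, 10, stratified = TRUE, seed = 1)
  for (k in 1:10) {
    expect_equal(sum(y[fs == k] == 1), 1)
    expect_equal(sum(y[fs == k] == 0), 1)
  }
  expect_identical(fs, make_folds(y, 10, stratified = TRUE, seed = 1))

  # class ratio preserved within one sample on uneven classes
  y2 <- rep(c(0, 1), c(105, 104))
  f2 <- make_folds(y2, 10, seed = 2)
  pos_per_fold <- tapply(y2, f2, sum)
  expect_lte(diff(range(pos_per_fold)), 1)

  expect_error(make_folds(rep(c(0, 1), c(18, 2)), 10, seed = 1), "stratify")
  expect_error(make_folds(c(0, 1), 10), "fewer samples")
})

test_that("classifier scores and labels behave as defined", {
  cl <- make_two_clusters(100, sep = 5, seed = 3)
  holdout <- make_two_clusters(40, sep = 5, seed = 4)
  for (kind in c("random_forest", "svm_rbf", "knn")) {
    pr <- fit_predict(kind, default_grids(4)[[kind]][1, , drop = FALSE],
                      cl$x, cl$y, holdout$x)
    expect_true(all(pr$score >= 0 & pr$score <= 1))
    expect_gte(mean(pr$label == holdout$y), 0.95)
    if (kind != "svm_rbf") {
      expect_equal(pr$label, as.integer(pr$score >= 0.5))
    }
  }
  expect_error(fit_predict("knn", list(k = 3), cl$x, cl$y, holdout$x[, 1:2]),
               "mismatch")
  expect_error(fit_predict("knn", list(k = 3), cl$x, rep(0, 100), holdout$x),
               "both classes")
})

test_that("KNN scores count positive neighbours", {
  # three training points at distance order 1,2,3 from the origin with
  # labels 1,1,0: k = 3 gives score 2/3 and label 1
  xtr <- rbind(c(1, 0), c(2, 0), c(3, 0))
  pr <- fit_predict("knn", list(k = 3), xtr, c(1, 1, 0), rbind(c(0, 0)))
  expect_equal(pr$score, 2 / 3)
  expect_equal(pr$label, 1L)

  # k = 1 on a test point equal to a training point returns its label
  pr1 <- fit_predict("knn", list(k = 1), xtr, c(1, 1, 0), rbind(c(3, 0)))
  expect_equal(pr1$label, 0L)
  expect_true(pr1$score %in% c(0, 1))
})

test_that("grid tuning picks the better region and respects single points", {
  g1 <- data.frame(k = 7)
  expect_identical(tune_classifier("knn", g1, matrix(0, 1, 1), 0), g1)

  cl <- make_two_clusters(60, sep = 5, seed = 5)
  chosen <- tune_classifier("knn", data.frame(k = c(1, 35)), cl$x, cl$y,
                            seed = 6)
  expect_equal(chosen$k, 1)
  expect_error(tune_classifier("knn", data.frame(k = c(1, 3)),
                               cl$x, rep(1, 60), seed = 1), "single-class")
  expect_error(tune_classifier("knn", data.frame(k = integer(0))[0, , drop = FALSE],
                               cl$x, cl$y), "empty")
})

test_that("label-permuted data yields chance-level CV accuracy", {
  set.seed(11)
  x <- matrix(runif(120 * 6), 120)
  colnames(x) <- paste0("f", 1:6)
  y <- sample(rep(c(0, 1), c(72, 48)))  # labels independent of x
  fit <- bv_ensemble(x, y, cv = cv_control(n_folds = 5, n_repeats = 10,
                                           base_seed = 13),
                     resample = NULL, tune = FALSE, fit_final = FALSE)
  maj <- max(mean(y == 0), mean(y == 1))
  for (m in c("random_forest", "svm_rbf", "knn")) {
    expect_lt(abs(fit$performance["accuracy", m] - maj), 0.12)
  }
})
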