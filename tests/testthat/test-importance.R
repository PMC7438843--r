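# One informative feature among noise: each ranker should find it.
make_planted <- function(n = 120, p = 6, seed = 30) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(runif(n * p), n, p)
  x[, 1] <- y * 0.8 + runif(n, 0, 0.2)  # near-perfectly predictive
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

test_that("random-forest permutation importance finds the planted feature", {
  d <- make_planted(200, 10)
  r <- rf_importance_ranks(d$x, d$y, seed = 31)
  expect_equal(sort(unname(r)), 1:10)
  expect_equal(unname(r["f1"]), 1L)
  # noise features sit in the lower half on average
  expect_gt(mean(r[-1]), 10 / 2)
})

test_that("SVM recursive elimination ranks the informative feature first", {
  d <- make_planted(80, 3)
  r <- svm_rfe_ranks(d$x, d$y, seed = 32)
  expect_equal(sort(unname(r)), 1:3)
  expect_equal(unname(r["f1"]), 1L)

  # a duplicated informative feature: one copy is eliminated early
  x2 <- cbind(d$x, f1_copy = d$x[, 1])
  r2 <- svm_rfe_ranks(x2, d$y, seed = 33)
  expect_gt(max(r2[c("f1", "f1_copy")]), 2)   # one copy is redundant
  expect_equal(min(r2[c("f1", "f1_copy")]), 1) # the other survives to the top
  expect_error(svm_rfe_ranks(d$x[, 1, drop = FALSE], d$y), "at least 2")
})

test_that("KNN leave-one-feature-out ranks the informative feature first", {
  d <- make_planted(150, 8)
  r <- knn_lofo_ranks(d$x, d$y, seed = 34)
  expect_equal(sort(unname(r)), 1:8)
  expect_equal(unname(r["f1"]), 1L)
  expect_error(knn_lofo_ranks(d$x[, 1, drop = FALSE], d$y), "at least 2")
})

test_that("rank averaging orders by mean rank with min-rank tie-breaking", {
  # consensus identity: all classifiers agree -> voting equals the input
  r <- data.frame(feature = c("a", "b", "c"),
                  rank_knn = c(2, 1, 3), rank_rf = c(2, 1, 3),
                  rank_svm = c(2, 1, 3))
  out <- average_ranks(r)
  expect_equal(out$feature, c("b", "a", "c"))
  expect_equal(out$voting_rank, 1:3)
  expect_equal(out$mean_rank[out$feature == "b"], 1)

  # tie on mean rank: the better single-classifier rank wins
  r2 <- data.frame(feature = c("late", "early"),
                   rank_knn = c(4, 1), rank_rf = c(2, 5),
                   rank_svm = c(3, 3))
  out2 <- average_ranks(r2)
  expect_equal(out2$feature, c("early", "late"))

  # tie on mean and min rank: label order decides
  r3 <- data.frame(feature = c("zeta", "alpha"),
                   rank_knn = c(1, 2), rank_rf = c(2, 1),
                   rank_svm = c(3, 3))
  expect_equal(average_ranks(r3)$feature, c("alpha", "zeta"))

  # invariant to permuting the three rank columns
  r4 <- data.frame(feature = letters[1:5],
                   rank_knn = c(3, 1, 5, 2, 4), rank_rf = c(2, 4, 1, 5, 3),
                   rank_svm = c(5, 2, 4, 1, 3))
  swapped <- data.frame(feature = r4$feature, rank_knn = r4$rank_svm,
                        rank_rf = r4$rank_knn, rank_svm = r4$rank_rf)
  expect_equal(average_ranks(r4)$feature, average_ranks(swapped)$feature)

  expect_error(average_ranks(r4[, -2]), "need columns")
  r5 <- r4; r5$rank_rf[2] <- NA
  expect_error(average_ranks(r5), "missing rank")
})

test_that("ensemble importance returns a coherent table and overlap listing", {
  d <- make_planted(100, 5)
  tab <- ensemble_importance(d$x, d$y, seed = 35)
  expect_s3_class(tab, "importance_table")
  expect_equal(sort(tab$voting_rank), 1:5)
  for (cl in c("rank_knn", "rank_rf", "rank_svm")) {
    expect_equal(sort(tab[[cl]]), 1:5)
  }
  expect_equal(tab$feature[1], "f1")
  ov <- importance_overlap(tab, k = 2)
  expect_true("f1" %in% ov$shared_all)
})
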