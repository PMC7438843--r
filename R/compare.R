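#' Permutation t-test comparing two AUC distributions
#'
#' Computes the Welch (unequal-variance) two-sample t statistic between two
#' vectors of per-repeat AUC values, then permutes the group labels
#' `n_permutations` times. The two-sided p-value uses the add-one
#' correction `p = (1 + #{|t*| >= |t|}) / (1 + n_permutations)`, so it is
#' never exactly zero and attains a minimum of `1/(1 + n_permutations)`.
#'
#' @param auc_a,auc_b numeric vectors of AUC values in `[0, 1]`, length >= 2.
#' @param n_permutations number of label permutations (default 1000).
#' @param seed optional integer seed.
#' @return object of class `"perm_t_test"`: `observed_statistic`,
#'   `mean_difference` (`mean(auc_a) - mean(auc_b)`), `p_value`,
#'   `n_permutations`, `seed`.
#' @examples
#' set.seed(1)
#' permutation_t_test(runif(20, 0.8, 0.9), runif(20, 0.8, 0.9),
#'                    n_permutations = 99)
#' @export
permutation_t_test <- function(auc_a, auc_b, n_permutations = 1000, seed = NULL) {
  if (length(auc_a) < 2L || length(auc_b) < 2L) {
    stop("both AUC vectors must have length at least 2")
  }
  if (any(c(auc_a, auc_b) < 0 | c(auc_a, auc_b) > 1)) {
    stop("AUC values must lie in [0, 1]")
  }
  pooled <- c(auc_a, auc_b)
  if (stats::var(pooled) == 0) {
    stop("all pooled values are identical; the t statistic is undefined. ",
         "Check that the two runs produced varying AUCs.")
  }
  n_a <- length(auc_a)
  n_b <- length(auc_b)
  t_obs <- welch_t(auc_a, auc_b)
  # permute over the sorted pool, always drawing the smaller group, so the
  # permuted |t| values — and hence p — are invariant to swapping the inputs
  pool_sorted <- sort(pooled)
  m <- min(n_a, n_b)
  t_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample(n_a + n_b, m)
      welch_t(pool_sorted[idx], pool_sorted[-idx])
    }, numeric(1))
  })
  p <- (1 + sum(abs(t_perm) >= abs(t_obs), na.rm = TRUE)) / (1 + n_permutations)
  structure(
    list(
      observed_statistic = t_obs,
      mean_difference = mean(auc_a) - mean(auc_b),
      p_value = p,
      n_permutations = as.integer(n_permutations),
      seed = seed
    ),
    class = "perm_t_test"
  )
}

# Welch two-sample t statistic; returns 0 when both group variances vanish
# and the means are equal (identical-groups permutations).
welch_t <- function(a, b) {
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  d <- mean(a) - mean(b)
  if (se2 == 0) {
    return(if (d == 0) 0 else sign(d) * Inf)
  }
  d / sqrt(se2)
}

#' @export
print.perm_t_test <- function(x, ...) {
  cat("Permutation t-test on AUC distributions\n")
  cat(sprintf("  Welch t = %.4f, mean difference = %.4f\n",
              x$observed_statistic, x$mean_difference))
  cat(sprintf("  p = %.4g (%d permutations, two-sided)\n",
              x$p_value, x$n_permutations))
  invisible(x)
}
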