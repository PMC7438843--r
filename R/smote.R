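#' SMOTE: synthetic minority oversampling
#'
#' Augments the minority class with synthetic points placed on segments
#' between a minority sample and one of its `k` nearest minority-class
#' neighbours (Euclidean distance in feature space): each synthetic point is
#' `x + u * (x' - x)` with `u ~ Uniform(0, 1)`. With `percent = 100` the
#' minority class doubles; in general `round(percent/100 * n_minority)`
#' synthetic points are created, parents being cycled through a random
#' permutation of the minority samples so the load is spread evenly.
#'
#' Features are assumed to be on comparable scales (e.g. min-max normalized,
#' see [minmax_normalize()]) so each feature contributes proportionately to
#' the distance.
#'
#' @param x samples x features numeric matrix.
#' @param y binary labels (0/1); the rarer class is the minority.
#' @param percent oversampling amount as a percentage of the minority size
#'   (default 100).
#' @param k number of nearest minority neighbours (default 5); must be
#'   smaller than the minority class size.
#' @param seed optional integer seed.
#' @return an object of class `"bv_resampled"`: a list with `x`, `y`,
#'   `provenance` (`"original"`/`"synthetic"` per row) and `parents`
#'   (two-column matrix of parent/neighbour row indices for synthetic rows,
#'   for auditing the convex-combination property).
#' @examples
#' x <- matrix(runif(40), 20)
#' y <- rep(c(0, 1), c(14, 6))
#' rs <- smote_oversample(x, y, percent = 100, k = 3, seed = 1)
#' table(rs$y)
#' @export
smote_oversample <- function(x, y, percent = 100, k = 5, seed = NULL) {
  y <- as_binary_labels(y)
  if (!is.matrix(x) || nrow(x) != length(y)) stop("'x' rows must match 'y' length")
  if (percent < 0) stop("'percent' must be non-negative")
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present for SMOTE")
  minority <- as.integer(names(tab)[which.min(tab)])
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  n_syn <- round(percent / 100 * n_min)
  prov <- rep("original", length(y))
  if (n_syn == 0) {
    return(structure(
      list(x = x, y = y, provenance = prov,
           parents = matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("parent", "neighbor")))),
      class = "bv_resampled"
    ))
  }
  if (n_min <= k) {
    stop(sprintf(
      "minority class size (%d) must exceed k = %d; lower 'k'", n_min, k
    ))
  }

  xm <- x[min_idx, , drop = FALSE]
  dm <- as.matrix(stats::dist(xm))
  diag(dm) <- Inf
  # k nearest minority neighbours of each minority point, ties by row order
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i) order(dm[i, ])[seq_len(k)]))

  out <- with_seed(seed, {
    parent_pool <- rep(sample(n_min), length.out = n_syn)
    syn <- matrix(NA_real_, n_syn, ncol(x))
    parents <- matrix(NA_integer_, n_syn, 2L,
                      dimnames = list(NULL, c("parent", "neighbor")))
    for (s in seq_len(n_syn)) {
      i <- parent_pool[s]
      j <- nn[i, sample.int(k, 1L)]
      u <- stats::runif(1L)
      syn[s, ] <- xm[i, ] + u * (xm[j, ] - xm[i, ])
      parents[s, ] <- c(min_idx[i], min_idx[j])
    }
    list(syn = syn, parents = parents)
  })
  colnames(out$syn) <- colnames(x)
  rownames(out$syn) <- sprintf("synthetic_%03d", seq_len(n_syn))
  structure(
    list(
      x = rbind(x, out$syn),
      y = c(y, rep(minority, n_syn)),
      provenance = c(prov, rep("synthetic", n_syn)),
      parents = out$parents
    ),
    class = "bv_resampled"
  )
}

#' Undersample the majority class
#'
#' Reduces the majority class to `target` rows by uniform random sampling
#' without replacement; minority rows (original and synthetic) are untouched
#' and row order is otherwise preserved.
#'
#' @param rs a `"bv_resampled"` object from [smote_oversample()], or a list
#'   with `x`, `y` and optionally `provenance`.
#' @param target majority size to keep: a positive integer, or
#'   `"balanced"` (default) to match the current minority size.
#' @param seed optional integer seed.
#' @return a `"bv_resampled"` object.
#' @export
undersample_majority <- function(rs, target = "balanced", seed = NULL) {
  y <- as_binary_labels(rs$y)
  prov <- rs$provenance %||% rep("original", length(y))
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present")
  majority <- as.integer(names(tab)[which.max(tab)])
  maj_idx <- which(y == majority)
  n_maj <- length(maj_idx)
  if (identical(target, "balanced")) target <- sum(y != majority)
  target <- as.integer(target)
  if (target < 1) stop("'target' must keep at least one majority sample")
  if (target > n_maj) {
    stop(sprintf("'target' (%d) exceeds current majority size (%d)", target, n_maj))
  }
  if (target == n_maj) {
    keep <- seq_along(y)
  } else {
    drop_set <- with_seed(seed, sample(maj_idx, n_maj - target))
    keep <- setdiff(seq_along(y), drop_set)
  }
  structure(
    list(
      x = rs$x[keep, , drop = FALSE],
      y = y[keep],
      provenance = prov[keep],
      parents = rs$parents
    ),
    class = "bv_resampled"
  )
}

#' Rebalancing control parameters
#'
#' @param smote_percent SMOTE oversampling percentage (default 100).
#' @param k_neighbors SMOTE neighbour count (default 5).
#' @param majority_target `"balanced"` or an explicit majority size kept
#'   after undersampling; `NA` disables undersampling.
#' @param mode `"pre_cv"` applies rebalancing once to the full training set
#'   before cross-validation (faithful to the original analysis, but note
#'   synthetic points then leak information across CV folds);
#'   `"within_fold"` rebalances each training fold only.
#' @param seed optional integer seed for the resampling draws.
#' @return a list of class `"resample_control"`.
#' @export
resample_control <- function(smote_percent = 100,
                             k_neighbors = 5,
                             majority_target = "balanced",
                             mode = c("pre_cv", "within_fold"),
                             seed = NULL) {
  structure(
    list(
      smote_percent = smote_percent,
      k_neighbors = k_neighbors,
      majority_target = majority_target,
      mode = match.arg(mode),
      seed = seed
    ),
    class = "resample_control"
  )
}

# Apply SMOTE then (optionally) undersampling under one control object.
rebalance <- function(x, y, control, seed = NULL) {
  seed <- control$seed %||% seed
  rs <- smote_oversample(x, y,
    percent = control$smote_percent,
    k = control$k_neighbors, seed = seed
  )
  tgt <- control$majority_target
  if (!(length(tgt) == 1L && is.na(tgt))) {
    rs <- undersample_majority(rs, target = tgt,
                               seed = if (is.null(seed)) NULL else seed + 1L)
  }
  rs
}

#' @export
print.bv_resampled <- function(x, ...) {
  tab <- table(x$y)
  cat("Rebalanced training set:", length(x$y), "rows (",
      sum(x$provenance == "synthetic"), "synthetic )\n")
  cat("  class counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
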