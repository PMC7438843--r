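#' Filter rare taxa by contribution to total reads
#'
#' Retains taxa contributing at least `min_fraction` of the table's grand
#' total of sequence reads (default 0.01%). The threshold is inclusive and
#' assessed on the raw counts over all samples of the table, so the rule is
#' idempotent and unaffected by later zero imputation.
#'
#' @param counts samples x taxa non-negative count matrix.
#' @param min_fraction minimum fraction of the grand total (default 1e-4).
#' @return the count matrix restricted to retained taxon columns, original
#'   column order preserved.
#' @examples
#' m <- cbind(a = c(999900, 0), b = c(0, 100))
#' colnames(filter_taxa(m))  # both retained: b has exactly 0.01%
#' @export
filter_taxa <- function(counts, min_fraction = 1e-4) {
  if (!is.matrix(counts) || !nrow(counts) || !ncol(counts)) {
    stop("'counts' must be a non-empty matrix")
  }
  if (any(counts < 0) || anyNA(counts)) stop("'counts' must be non-negative and complete")
  if (min_fraction < 0 || min_fraction >= 1) stop("'min_fraction' must be in [0, 1)")
  keep <- colSums(counts) >= min_fraction * sum(counts)
  if (!any(keep)) stop("all taxa removed by the abundance filter")
  site <- attr(counts, "site")
  out <- counts[, keep, drop = FALSE]
  attr(out, "site") <- site
  out
}

#' Replace zero counts by small uniform draws
#'
#' Each zero cell is replaced by an independent draw from
#' Uniform(`low`, `high`) so every entry is strictly positive ahead of the
#' log-ratio transform; nonzero cells are returned unchanged.
#'
#' @param counts non-negative count matrix.
#' @param low,high uniform interval bounds (defaults 0.5 and 0.95).
#' @param seed optional integer seed.
#' @return numeric matrix of the same shape, strictly positive.
#' @export
impute_zeros <- function(counts, low = 0.5, high = 0.95, seed = NULL) {
  if (!(0 < low && low < high && high < 1)) {
    stop("need 0 < low < high < 1 for the imputation interval")
  }
  if (any(counts < 0)) stop("'counts' must be non-negative")
  out <- counts * 1.0
  zero <- which(out == 0)
  if (length(zero)) {
    out[zero] <- with_seed(seed, stats::runif(length(zero), low, high))
  }
  out
}

#' Centered log-ratio transform
#'
#' Per sample (row), maps a strictly positive composition `x` to
#' `log(x) - mean(log(x))`, i.e. the log ratio to the row's geometric mean.
#' Each output row sums to zero; the transform is invariant to row scaling.
#'
#' @param x strictly positive numeric matrix (run [impute_zeros()] first).
#' @return numeric matrix of the same shape with zero row sums.
#' @export
clr_transform <- function(x) {
  if (any(x <= 0) || anyNA(x)) {
    stop("all entries must be strictly positive; impute zeros before the CLR transform")
  }
  lx <- log(x)
  sweep(lx, 1L, rowMeans(lx), `-`)
}

#' Min-max normalization per feature
#'
#' Rescales every feature column to `[0, 1]` via
#' `x_new = (x - x_min) / (x_max - x_min)` using the column's minimum and
#' maximum over all samples. A constant column (zero range) maps to all
#' zeros.
#'
#' @param x numeric matrix, samples x features.
#' @return numeric matrix with all values in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (!nrow(x)) stop("need at least one sample")
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  rng <- maxs - mins
  out <- sweep(x, 2L, mins, `-`)
  pos <- rng > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2L, rng[pos], `/`)
  out[, !pos] <- 0
  out
}

#' Assemble the classifier feature matrix from a built cohort
#'
#' Runs the preprocessing pipeline in the fixed order
#' filter -> impute -> CLR -> min-max, and optionally appends the male
#' partner's circumcision status as a binary feature (already in `[0, 1]`,
#' appended after normalization).
#'
#' @param cohort list from [build_cohort()] (`counts`, `labels`, `metadata`).
#' @param min_fraction taxon filter threshold (default 1e-4).
#' @param impute_low,impute_high zero-imputation interval (defaults 0.5, 0.95).
#' @param include_circumcision append the `Circumcised` feature (default TRUE).
#' @param seed optional seed for the imputation draws.
#' @return list with `x` (samples x features matrix, values in `[0, 1]`) and
#'   `y` (integer labels, 1 = incident BV).
#' @export
assemble_features <- function(cohort,
                              min_fraction = 1e-4,
                              impute_low = 0.5,
                              impute_high = 0.95,
                              include_circumcision = TRUE,
                              seed = NULL) {
  counts <- filter_taxa(cohort$counts, min_fraction)
  imp <- impute_zeros(counts, impute_low, impute_high, seed = seed)
  x <- minmax_normalize(clr_transform(imp))
  if (include_circumcision) {
    if (is.null(cohort$metadata$circumcised)) {
      stop("metadata lacks a 'circumcised' column")
    }
    x <- cbind(x, Circumcised = as.numeric(cohort$metadata$circumcised))
  }
  list(x = x, y = as.integer(cohort$labels))
}
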