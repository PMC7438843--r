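# Internal helpers shared across the package.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded package
#' functions do not disturb the global RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Draw a fresh sub-seed from the current RNG stream (for backends such as
# ranger that take an explicit seed rather than reading R's RNG).
draw_seed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

# Coerce labels to an integer 0/1 vector; errors unless exactly two levels
# (or a subset of {0, 1}) are present or representable.
as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c("0", "1"))) {
      stop("labels must be coded 0/1, got: ", paste(u, collapse = ", "))
    }
    y <- as.integer(y)
  }
  if (!is.numeric(y) || anyNA(y) || !all(y %in% c(0, 1))) {
    stop("labels must be binary 0/1 without missing values")
  }
  as.integer(y)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used only to stamp output files with a configuration fingerprint.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor the low byte only (b < 256), keeping h a double in [0, 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # multiply by the FNV prime 16777619 modulo 2^32, split to stay exact
    # in double arithmetic (no intermediate exceeds 2^53)
    h <- ((h %% 65536) * 16777619 +
            (((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name))
  }
}
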