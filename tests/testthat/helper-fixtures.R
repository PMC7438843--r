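# Shared fixtures built in code at test time.

# A deterministic couples metadata table rebuilt from the printed cohort
# arithmetic of the study design this package emulates:
#   211 couples; 43 with baseline Nugent 7-10 (excluded);
#   168 retained: 142 baseline 0-3 (37 incident: 13 at month 1, 16 at month
#   6, 8 at month 12) and 26 baseline 4-6 (15 incident: 10/4/1);
#   99 circumcised men of whom 26 partners had incident BV.
make_reference_metadata <- function() {
  rows <- list()
  add <- function(n, baseline, m1, m6, m12) {
    if (n > 0) rows[[length(rows) + 1L]] <<- data.frame(
      n = n, baseline = baseline, m1 = m1, m6 = m6, m12 = m12
    )
  }
  # excluded: baseline BV
  add(43, 8, 2, 2, 2)
  # baseline 0-3 incident: first incident visit at months 1 / 6 / 12
  add(13, 2, 8, 3, 3)
  add(16, 2, 3, 8, 3)
  add(8, 2, 3, 3, 8)
  # baseline 0-3 persistent negative
  add(142 - 37, 2, 3, 3, 3)
  # baseline 4-6 incident
  add(10, 5, 8, 3, 3)
  add(4, 5, 3, 8, 3)
  add(1, 5, 3, 3, 8)
  # baseline 4-6 persistent negative
  add(26 - 15, 5, 3, 3, 3)
  blocks <- do.call(rbind, rows)
  md <- blocks[rep(seq_len(nrow(blocks)), blocks$n), -1L]
  md <- data.frame(
    couple_id = sprintf("ref_%03d", seq_len(nrow(md))),
    circumcised = 0L,
    nugent_m0 = md$baseline, nugent_m1 = md$m1,
    nugent_m6 = md$m6, nugent_m12 = md$m12,
    row.names = NULL
  )
  # assign 99 circumcised among the 168 retained couples, 26 of them with
  # incident outcomes (52 incident couples in total among the retained)
  retained <- md$nugent_m0 <= 6
  incident <- retained & (md$nugent_m1 >= 7 | md$nugent_m6 >= 7 | md$nugent_m12 >= 7)
  md$circumcised[which(incident)[1:26]] <- 1L
  md$circumcised[which(retained & !incident)[1:73]] <- 1L
  md
}

# Tiny well-separated two-class dataset for classifier sanity checks.
make_two_clusters <- function(n = 100, p = 4, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[y == 1L, 1:2] <- x[y == 1L, 1:2] + sep
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

# Brute-force AUC oracle: pairwise comparison of all positive-negative pairs.
auc_brute <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
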