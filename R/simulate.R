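#' Simulate a couples cohort with baseline penile microbiome counts
#'
#' Generates a synthetic cohort of heterosexual couples in which each man
#' contributes one baseline penile microbiome sample (a sparse compositional
#' taxa count vector) and each woman contributes longitudinal Nugent scores
#' at months 0, 1, 6 and 12. The woman's incident-BV outcome is drawn first;
#' taxa abundances and Nugent trajectories are then generated consistent with
#' it, so the outcome can be recovered exactly by [derive_outcome()].
#'
#' Compositions follow a Dirichlet-multinomial model: a per-couple taxon
#' composition is drawn from a Dirichlet with concentrations
#' `base_concentrations`; for couples with an incident outcome, the
#' concentrations of `effect_taxa` are multiplied by `exp(effect_shift)`.
#' Multiplying concentrations (rather than shifting counts post hoc) keeps
#' the composition closed. Sequencing depth per sample is log-normal with
#' parameters solved from the target median and interquartile range:
#' `meanlog = log(depth_median)` and
#' `sdlog = log(depth_iqr[2]/depth_iqr[1]) / (2 * qnorm(0.75))`, which
#' reproduces both printed summaries exactly with the model's two free
#' parameters.
#'
#' @param n_couples number of couples (one sample per couple).
#' @param n_taxa number of taxa in the count table.
#' @param incidence probability a couple's outcome is incident BV
#'   (default 0.31, matching the cohort this design emulates).
#' @param p_circumcised probability the male partner is circumcised
#'   (default 0.59).
#' @param effect_taxa integer indices of taxa whose abundance differs by
#'   future BV status (default none).
#' @param effect_shift natural-log fold shift applied to the Dirichlet
#'   concentration of each effect taxon in incident couples; recycled to
#'   `length(effect_taxa)`.
#' @param base_concentrations positive Dirichlet concentrations, length
#'   `n_taxa`. The default is a power-law profile (total concentration 5,
#'   weights proportional to `rank^-1.5`) producing the steep
#'   abundance/presence gradient typical of penile 16S count tables.
#' @param depth_median target median sequencing depth (default 25997).
#' @param depth_iqr target depth interquartile range, a length-2 vector
#'   (default `c(19524, 33779)`).
#' @param p_intermediate probability a retained couple's baseline Nugent
#'   score is intermediate (4-6) rather than normal (0-3); default 0.155.
#' @param seed integer seed for reproducibility, or `NULL`.
#'
#' @return a list with components:
#'   \item{counts}{`n_couples` x `n_taxa` integer matrix, rows named by
#'     couple id, columns by taxon label, with a `"site"` attribute.}
#'   \item{metadata}{data frame with `couple_id`, `circumcised` (0/1) and
#'     Nugent columns `nugent_m0`, `nugent_m1`, `nugent_m6`, `nugent_m12`.}
#' @examples
#' sim <- simulate_cohort(40, n_taxa = 20, seed = 1)
#' dim(sim$counts)
#' @export
simulate_cohort <- function(n_couples,
                            n_taxa = 50,
                            incidence = 0.31,
                            p_circumcised = 0.59,
                            effect_taxa = integer(0),
                            effect_shift = 1.5,
                            base_concentrations = NULL,
                            depth_median = 25997,
                            depth_iqr = c(19524, 33779),
                            p_intermediate = 0.155,
                            seed = NULL) {
  if (!is.numeric(n_couples) || n_couples < 1) stop("'n_couples' must be a positive integer")
  if (!is.numeric(n_taxa) || n_taxa < 1) stop("'n_taxa' must be a positive integer")
  n_couples <- as.integer(n_couples)
  n_taxa <- as.integer(n_taxa)
  stopifnot_prob(incidence, "incidence")
  stopifnot_prob(p_circumcised, "p_circumcised")
  stopifnot_prob(p_intermediate, "p_intermediate")
  effect_taxa <- as.integer(effect_taxa)
  if (length(effect_taxa) && (any(effect_taxa < 1) || any(effect_taxa > n_taxa))) {
    stop("'effect_taxa' indices must lie in 1..n_taxa")
  }
  if (length(effect_taxa)) {
    effect_shift <- rep_len(effect_shift, length(effect_taxa))
  }
  if (is.null(base_concentrations)) {
    w <- (seq_len(n_taxa))^(-1.5)
    base_concentrations <- 5 * w / sum(w)
  }
  if (length(base_concentrations) != n_taxa || any(base_concentrations <= 0)) {
    stop("'base_concentrations' must be ", n_taxa, " positive values")
  }
  dp <- depth_lognormal_params(depth_median, depth_iqr)

  with_seed(seed, {
    outcome <- stats::rbinom(n_couples, 1L, incidence)
    circ <- stats::rbinom(n_couples, 1L, p_circumcised)
    depth <- pmax(1L, as.integer(round(stats::rlnorm(n_couples, dp$meanlog, dp$sdlog))))

    counts <- matrix(0L, n_couples, n_taxa)
    for (i in seq_len(n_couples)) {
      alpha <- base_concentrations
      if (outcome[i] == 1L && length(effect_taxa)) {
        alpha[effect_taxa] <- alpha[effect_taxa] * exp(effect_shift)
      }
      g <- stats::rgamma(n_taxa, shape = alpha, rate = 1)
      p <- g / sum(g)
      counts[i, ] <- as.integer(stats::rmultinom(1L, depth[i], p))
    }
    rownames(counts) <- sprintf("couple_%03d", seq_len(n_couples))
    colnames(counts) <- sprintf("taxon_%02d", seq_len(n_taxa))
    attr(counts, "site") <- "meatal"

    nugent <- synth_nugent(outcome, p_intermediate)
    metadata <- data.frame(
      couple_id = rownames(counts),
      circumcised = circ,
      nugent_m0 = nugent$m0,
      nugent_m1 = nugent$m1,
      nugent_m6 = nugent$m6,
      nugent_m12 = nugent$m12,
      stringsAsFactors = FALSE
    )
    list(counts = counts, metadata = metadata)
  })
}

# Solve log-normal depth parameters from a median and IQR. The median pins
# meanlog; the IQR ratio pins sdlog.
depth_lognormal_params <- function(depth_median, depth_iqr) {
  if (length(depth_iqr) != 2L || any(depth_iqr <= 0) || depth_median <= 0) {
    stop("depth parameters must be positive; 'depth_iqr' must have length 2")
  }
  if (!(depth_iqr[1] < depth_median && depth_median < depth_iqr[2])) {
    stop("impossible depth parameters: need depth_iqr[1] < depth_median < depth_iqr[2]")
  }
  list(
    meanlog = log(depth_median),
    sdlog = log(depth_iqr[2] / depth_iqr[1]) / (2 * stats::qnorm(0.75))
  )
}

# Minimal Nugent trajectory synthesis. Only the categories 0-3 / 4-6 / 7-10
# matter downstream; exact integers are drawn uniformly within category.
# All couples are generated BV-negative at baseline (this simulator emulates
# the at-risk cohort); incident couples receive a 7-10 score at one random
# follow-up month among {1, 6, 12}, with earlier follow-ups kept at 0-6 so
# the drawn month is the first incident visit.
synth_nugent <- function(outcome, p_intermediate) {
  n <- length(outcome)
  baseline_cat <- stats::rbinom(n, 1L, p_intermediate) # 1 = intermediate
  m0 <- ifelse(baseline_cat == 1L,
    sample(4:6, n, replace = TRUE),
    sample(0:3, n, replace = TRUE)
  )
  months <- c(1L, 6L, 12L)
  fu <- matrix(sample(0:6, 3L * n, replace = TRUE), nrow = n)
  for (i in which(outcome == 1L)) {
    v <- sample(3L, 1L)
    fu[i, v] <- sample(7:10, 1L)
    if (v < 3L) {
      # later visits unconstrained once the first incident visit is set
      later <- (v + 1L):3L
      fu[i, later] <- sample(0:10, length(later), replace = TRUE)
    }
  }
  list(m0 = as.integer(m0), m1 = fu[, 1L], m6 = fu[, 2L], m12 = fu[, 3L])
}
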