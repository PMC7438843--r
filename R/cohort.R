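#' Derive the incident-BV outcome from longitudinal Nugent scores
#'
#' Classifies each couple by the female partner's Nugent trajectory. Incident
#' BV is a Nugent score of 7-10 at a follow-up visit (months 1, 6 or 12)
#' following a score of 0-6 at baseline (month 0). Couples with baseline
#' 7-10 are excluded from the incidence analysis; couples with no attended
#' follow-up visit cannot contribute incidence and are excluded; under the
#' sensitivity analysis, couples with an intermediate baseline score (4-6)
#' are additionally excluded. Only the first incident visit defines the
#' outcome; later episodes are ignored.
#'
#' @param metadata data frame with columns `couple_id`, `nugent_m0` and
#'   optionally `nugent_m1`, `nugent_m6`, `nugent_m12` (NA = visit not
#'   attended), as returned by [simulate_cohort()] or [read_metadata()].
#' @param sensitivity logical; if `TRUE`, exclude intermediate baselines.
#' @return `metadata` with two added columns: `outcome`, one of
#'   `"excluded_baseline_bv"`, `"excluded_intermediate"`,
#'   `"excluded_no_followup"`, `"persistent_negative"`, `"incident"`; and
#'   `time_to_incident_months` (1, 6 or 12; NA unless incident).
#' @examples
#' md <- data.frame(couple_id = "c1", nugent_m0 = 3, nugent_m1 = 2,
#'                  nugent_m6 = 8, nugent_m12 = NA)
#' derive_outcome(md)
#' @export
derive_outcome <- function(metadata, sensitivity = FALSE) {
  if (!is.data.frame(metadata)) stop("'metadata' must be a data frame")
  if (!"nugent_m0" %in% names(metadata)) stop("missing baseline column 'nugent_m0'")
  fu_cols <- c(nugent_m1 = 1L, nugent_m6 = 6L, nugent_m12 = 12L)
  score_cols <- c("nugent_m0", names(fu_cols)[names(fu_cols) %in% names(metadata)])
  for (cl in score_cols) {
    s <- metadata[[cl]]
    bad <- !is.na(s) & (s < 0 | s > 10 | s != round(s))
    if (any(bad)) {
      stop(sprintf(
        "Nugent score outside 0-10 in column '%s' (couple %s)",
        cl, metadata$couple_id[which(bad)[1]]
      ))
    }
  }
  if (anyNA(metadata$nugent_m0)) {
    stop(
      "missing baseline Nugent score for couple ",
      metadata$couple_id[which(is.na(metadata$nugent_m0))[1]]
    )
  }

  n <- nrow(metadata)
  outcome <- character(n)
  time_to <- rep(NA_integer_, n)
  present <- names(fu_cols)[names(fu_cols) %in% names(metadata)]
  fu <- if (length(present)) {
    as.matrix(metadata[, present, drop = FALSE])
  } else {
    matrix(NA_real_, n, 0)
  }
  fu_months <- fu_cols[present]

  for (i in seq_len(n)) {
    b <- metadata$nugent_m0[i]
    scores <- fu[i, ]
    attended <- which(!is.na(scores))
    if (b >= 7) {
      outcome[i] <- "excluded_baseline_bv"
    } else if (sensitivity && b >= 4) {
      outcome[i] <- "excluded_intermediate"
    } else if (!length(attended)) {
      outcome[i] <- "excluded_no_followup"
    } else {
      hit <- attended[scores[attended] >= 7]
      if (length(hit)) {
        outcome[i] <- "incident"
        time_to[i] <- fu_months[[hit[1]]]
      } else {
        outcome[i] <- "persistent_negative"
      }
    }
  }
  metadata$outcome <- outcome
  metadata$time_to_incident_months <- time_to
  metadata
}

#' Build the analysis cohort: retained couples and binary labels
#'
#' Applies [derive_outcome()] and restricts the count table and metadata to
#' couples whose outcome is `persistent_negative` (label 0) or `incident`
#' (label 1), preserving the input row order.
#'
#' @param metadata couple metadata data frame (see [derive_outcome()]).
#' @param counts samples x taxa count matrix with row names matching
#'   `metadata$couple_id`.
#' @param sensitivity logical; exclude intermediate baselines if `TRUE`.
#' @return list with `counts` (restricted matrix), `labels` (named integer
#'   0/1 vector), and `metadata` (restricted, with outcome columns).
#' @export
build_cohort <- function(metadata, counts, sensitivity = FALSE) {
  md <- derive_outcome(metadata, sensitivity = sensitivity)
  keep <- md$outcome %in% c("persistent_negative", "incident")
  md_keep <- md[keep, , drop = FALSE]
  if (nrow(md_keep)) {
    missing <- setdiff(md_keep$couple_id, rownames(counts))
    if (length(missing)) {
      stop("no count row for couple(s): ", paste(missing, collapse = ", "))
    }
    counts_keep <- counts[md_keep$couple_id, , drop = FALSE]
  } else {
    counts_keep <- counts[integer(0), , drop = FALSE]
  }
  labels <- as.integer(md_keep$outcome == "incident")
  names(labels) <- md_keep$couple_id
  list(counts = counts_keep, labels = labels, metadata = md_keep)
}
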