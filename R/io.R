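#' Read a taxa count table
#'
#' Tab- or comma-separated text; first column sample id, header row of taxon
#' labels, integer cells. Duplicate sample ids or taxon labels, non-integer
#' cells and empty tables are rejected with informative errors.
#'
#' @param path file path.
#' @param site anatomic-site tag attached to the table (default "meatal").
#' @return integer matrix, samples x taxa, with a `"site"` attribute.
#' @export
read_count_table <- function(path, site = "meatal") {
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, comment.char = "#",
    colClasses = "character", check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!nrow(df)) stop("no samples in ", path)
  ids <- df[[1L]]
  taxa <- names(df)[-1L]
  if (anyDuplicated(ids)) stop("duplicate sample id: ", ids[duplicated(ids)][1])
  if (anyDuplicated(taxa)) stop("duplicate taxon label: ", taxa[duplicated(taxa)][1])
  m <- matrix(NA_integer_, nrow(df), length(taxa),
              dimnames = list(ids, taxa))
  for (j in seq_along(taxa)) {
    v <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(v))
    bad <- is.na(num) | num != round(num) | num < 0
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "non-integer count '%s' at sample '%s', taxon '%s'",
        v[i], ids[i], taxa[j]
      ))
    }
    m[, j] <- as.integer(num)
  }
  attr(m, "site") <- site
  m
}

#' Write a taxa count table
#'
#' @param counts samples x taxa integer matrix with dimnames.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_count_table <- function(counts, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read couple metadata
#'
#' Expected columns: `couple_id`, `circumcised` (0/1), `nugent_m0`, and
#' optionally `nugent_m1`, `nugent_m6`, `nugent_m12`. Blank follow-up cells
#' mark unattended visits (NA, not zero). Scores outside 0-10 and a missing
#' baseline column are rejected.
#'
#' @param path file path (tab- or comma-separated).
#' @return data frame of couple records.
#' @export
read_metadata <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, comment.char = "#",
    na.strings = c("", "NA"), check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!all(c("couple_id", "nugent_m0") %in% names(df))) {
    stop("metadata must contain 'couple_id' and a baseline 'nugent_m0' column")
  }
  for (cl in intersect(c("nugent_m0", "nugent_m1", "nugent_m6", "nugent_m12"),
                       names(df))) {
    s <- df[[cl]]
    bad <- !is.na(s) & (s < 0 | s > 10 | s != round(s))
    if (any(bad)) {
      stop(sprintf("Nugent score outside 0-10 in column '%s' (couple %s)",
                   cl, df$couple_id[which(bad)[1]]))
    }
    df[[cl]] <- as.integer(s)
  }
  df
}

#' Write a feature (or resampled training) matrix as tab-separated text
#'
#' @param x samples x features numeric matrix.
#' @param path output path.
#' @param provenance optional per-row `"original"`/`"synthetic"` flags,
#'   written as a leading column (see [smote_oversample()]).
#' @export
write_feature_matrix <- function(x, path, provenance = NULL) {
  df <- data.frame(
    sample_id = rownames(x) %||% sprintf("s%03d", seq_len(nrow(x))),
    x, check.names = FALSE
  )
  if (!is.null(provenance)) df <- cbind(df[1], provenance = provenance, df[-1])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an AUC vector file (one value per line)
#'
#' @param path file path; lines starting with `#` are ignored.
#' @return numeric vector of AUC values in `[0, 1]`.
#' @export
read_auc_vector <- function(path) {
  v <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  if (any(v < 0 | v > 1)) stop("AUC values must lie in [0, 1]: ", path)
  v
}

#' Write couple metadata
#'
#' @param metadata data frame of couple records.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_metadata <- function(metadata, path, sep = "\t") {
  utils::write.table(metadata, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Append a config-hash comment line to an output table.
stamp_file <- function(path, hash) {
  cat(sprintf("# config_hash %s\n", hash), file = path, append = TRUE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Returns the full default [run_pipeline()] configuration as a nested list;
#' supplied values (e.g. parsed from a YAML file) override defaults
#' shallowly per section.
#'
#' @param config partial configuration list, or a path to a YAML file.
#' @return complete configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    counts = NULL, metadata = NULL, output_dir = NULL,
    site = "meatal", sensitivity_mode = FALSE, seed = 1L,
    preprocess = list(min_fraction = 1e-4, impute_low = 0.5,
                      impute_high = 0.95, include_circumcision = TRUE),
    resample = list(enabled = TRUE, smote_percent = 100, k_neighbors = 5,
                    majority_target = "balanced", mode = "pre_cv"),
    cv = list(n_folds = 10, n_repeats = 50, stratified = TRUE),
    tune = TRUE, voting_mode = "mean", importance = TRUE
  )
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      defaults[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  defaults
}

#' Run the full prediction pipeline
#'
#' Executes cohort derivation, preprocessing, rebalancing, repeated-CV
#' ensemble evaluation and (optionally) variable importance from a single
#' configuration, and writes the performance summary, importance table,
#' per-repeat AUC vectors and a run manifest to `output_dir` (when set).
#' Every output table ends with a comment line carrying a hash of the
#' configuration, and the manifest (config echo, seed, stage dimensions,
#' package version) suffices to re-run the pipeline identically.
#'
#' @param config configuration list or YAML path; see [pipeline_config()].
#'   `counts`/`metadata` entries may be file paths or in-memory objects.
#' @return (invisibly) a list with the `bv_ensemble` fit, the importance
#'   table (or NULL), and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  counts <- cfg$counts
  metadata <- cfg$metadata
  if (is.character(counts)) counts <- read_count_table(counts, site = cfg$site)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.null(counts) || is.null(metadata)) {
    stop("config must provide 'counts' and 'metadata' (paths or objects)")
  }
  cfg_echo <- cfg
  cfg_echo$counts <- NULL; cfg_echo$metadata <- NULL
  hash <- fnv1a_hash(paste(deparse(cfg_echo), collapse = ""))

  cohort <- build_cohort(metadata, counts, sensitivity = cfg$sensitivity_mode)
  if (!length(cohort$labels)) stop("cohort stage retained no couples")
  feats <- assemble_features(cohort,
    min_fraction = cfg$preprocess$min_fraction,
    impute_low = cfg$preprocess$impute_low,
    impute_high = cfg$preprocess$impute_high,
    include_circumcision = cfg$preprocess$include_circumcision,
    seed = cfg$seed
  )
  resample <- if (isTRUE(cfg$resample$enabled)) {
    resample_control(
      smote_percent = cfg$resample$smote_percent,
      k_neighbors = cfg$resample$k_neighbors,
      majority_target = cfg$resample$majority_target,
      mode = cfg$resample$mode,
      seed = cfg$seed
    )
  }
  fit <- bv_ensemble(feats$x, feats$y,
    cv = cv_control(cfg$cv$n_folds, cfg$cv$n_repeats, cfg$cv$stratified,
                    base_seed = cfg$seed),
    resample = resample, tune = isTRUE(cfg$tune),
    voting_mode = cfg$voting_mode, fit_final = FALSE
  )
  imp <- NULL
  if (isTRUE(cfg$importance)) {
    imp <- ensemble_importance(fit$training$x, fit$training$y, seed = cfg$seed)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bvote")),
    r_version = as.character(getRversion()),
    config = cfg_echo,
    config_hash = hash,
    dimensions = list(
      input_couples = nrow(metadata),
      retained_couples = length(cohort$labels),
      incident = sum(cohort$labels == 1L),
      features = ncol(feats$x),
      training_rows = nrow(fit$training$x),
      synthetic_rows = sum(fit$training$provenance == "synthetic")
    ),
    performance = as.list(as.data.frame(fit$performance)),
    voting_auc_mean = unname(fit$performance["auc", "voting"])
  )

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    perf_path <- file.path(cfg$output_dir, "performance.tsv")
    utils::write.table(
      data.frame(metric = rownames(fit$performance), fit$performance,
                 check.names = FALSE),
      perf_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
    stamp_file(perf_path, hash)
    auc_path <- file.path(cfg$output_dir, "auc_distribution.tsv")
    utils::write.table(
      data.frame(repeat_index = seq_len(nrow(fit$auc_distribution)),
                 fit$auc_distribution, check.names = FALSE),
      auc_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
    stamp_file(auc_path, hash)
    if (!is.null(imp)) {
      imp_path <- file.path(cfg$output_dir, "importance.tsv")
      utils::write.table(as.data.frame(imp), imp_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      stamp_file(imp_path, hash)
    }
    yaml::write_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  }
  invisible(list(fit = fit, importance = imp, manifest = manifest))
}

#' Published per-classifier importance ranks for 20 meatal taxa
#'
#' Loads the package's bundled table of per-classifier variable-importance
#' ranks (KNN, random forest, SVM) for the 20 top-voted meatal taxa from a
#' couples cohort study of the penile microbiome and incident BV. Used as a
#' worked input for [average_ranks()].
#'
#' @return data frame with columns `feature`, `rank_knn`, `rank_rf`,
#'   `rank_svm`.
#' @export
meatal_rank_table <- function() {
  path <- system.file("extdata", "meatal_taxa_ranks.tsv", package = "bvote")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
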