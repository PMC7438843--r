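test_that("count tables round-trip through the text format", {
  sim <- simulate_cohort(12, n_taxa = 6, seed = 40)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(sim$counts, path)
  back <- read_count_table(path)
  expect_equal(unclass(back)[, ], unclass(sim$counts)[, ])

  # comma-separated input is detected too
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_count_table(sim$counts, path2, sep = ",")
  expect_equal(dim(read_count_table(path2)), dim(sim$counts))
})

test_that("malformed count tables are rejected with the cell named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttaxon_a\ttaxon_b", "s1\t3\t12.5"), path)
  expect_error(read_count_table(path), "12.5.*s1.*taxon_b")

  writeLines("sample_id\ttaxon_a\ttaxon_b", path)
  expect_error(read_count_table(path), "no samples")

  writeLines(c("sample_id\ttaxon_a\ttaxon_b",
               "s1\t1\t2", "s1\t3\t4"), path)
  expect_error(read_count_table(path), "duplicate sample id")
})

test_that("metadata round-trips and blank follow-ups stay missing", {
  md <- data.frame(
    couple_id = c("c1", "c2"), circumcised = c(1L, 0L),
    nugent_m0 = c(3L, 5L), nugent_m1 = c(2L, NA),
    nugent_m6 = c(NA_integer_, 7L), nugent_m12 = c(0L, NA)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(md, path)
  back <- read_metadata(path)
  expect_equal(back, md)
  expect_true(is.na(back$nugent_m6[1]))

  md_bad <- md; md_bad$nugent_m0[1] <- 11L
  write_metadata(md_bad, path)
  expect_error(read_metadata(path), "0-10")

  write_metadata(md[, -3], path)
  expect_error(read_metadata(path), "nugent_m0")
})

test_that("feature matrices and AUC vectors round-trip as plain text", {
  x <- matrix(runif(12), 4, dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(x, path, provenance = rep(c("original", "synthetic"), 2))
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$provenance, rep(c("original", "synthetic"), 2))
  expect_equal(as.matrix(back[, 3:5]), x, ignore_attr = TRUE)

  apath <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# voting AUC per repeat", "0.81", "0.9", "0.77"), apath)
  expect_equal(read_auc_vector(apath), c(0.81, 0.9, 0.77))
  writeLines("1.4", apath)
  expect_error(read_auc_vector(apath), "\\[0, 1\\]")
})

test_that("the pipeline runs end to end, deterministically, with a manifest", {
  sim <- simulate_cohort(60, n_taxa = 15, effect_taxa = 1:3, seed = 50)
  outdir <- withr::local_tempdir()
  cfg <- list(
    counts = sim$counts, metadata = sim$metadata, output_dir = outdir,
    seed = 5,
    cv = list(n_folds = 5, n_repeats = 2),
    resample = list(mode = "pre_cv"),
    tune = FALSE, importance = FALSE
  )
  res1 <- run_pipeline(cfg)
  res2 <- run_pipeline(cfg)
  expect_identical(res1$fit$performance, res2$fit$performance)
  expect_identical(res1$manifest$voting_auc_mean, res2$manifest$voting_auc_mean)

  expect_true(file.exists(file.path(outdir, "performance.tsv")))
  expect_true(file.exists(file.path(outdir, "auc_distribution.tsv")))
  expect_true(file.exists(file.path(outdir, "manifest.yaml")))

  # output tables end with the config-hash comment line
  perf_lines <- readLines(file.path(outdir, "performance.tsv"))
  expect_match(perf_lines[length(perf_lines)], "^# config_hash [0-9a-f]{8}$")
  manifest <- yaml::read_yaml(file.path(outdir, "manifest.yaml"))
  expect_match(perf_lines[length(perf_lines)], manifest$config_hash, fixed = TRUE)

  # manifest records the stage dimensions
  ch <- build_cohort(sim$metadata, sim$counts)
  expect_equal(manifest$dimensions$input_couples, 60)
  expect_equal(manifest$dimensions$retained_couples, length(ch$labels))
  expect_equal(manifest$dimensions$incident, sum(ch$labels))
  expect_equal(manifest$dimensions$training_rows, nrow(res1$fit$training$x))
})

test_that("sensitivity mode drops exactly the intermediate-baseline couples", {
  sim <- simulate_cohort(80, n_taxa = 10, seed = 51, p_intermediate = 0.3)
  main <- build_cohort(sim$metadata, sim$counts)
  sens <- build_cohort(sim$metadata, sim$counts, sensitivity = TRUE)
  n_intermediate <- sum(main$metadata$nugent_m0 >= 4 &
                          main$metadata$nugent_m0 <= 6)
  expect_equal(length(main$labels) - length(sens$labels), n_intermediate)
})
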