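test_that("roi_ts enforces its invariants with specific error classes", {
  expect_s3_class(roi_ts(matrix(1:20, 10, 2), 2, "s", "case"), "roi_ts")
  m <- matrix(rnorm(20), 10, 2)
  m[3, 2] <- NA
  expect_error(roi_ts(m, 2, "s", "case"), class = "dfcp_parse_error")
  expect_error(roi_ts(matrix(1:2, 1, 2), 2, "s", "case"),
               class = "dfcp_validation_error")
  expect_error(roi_ts(matrix(rnorm(20), 10, 2), -1, "s", "case"),
               class = "dfcp_metadata_error")
  expect_error(roi_ts(matrix(rnorm(20), 10, 2), 2, "s", "patient"))
})

test_that("time-series write/read round-trips bit-identically", {
  dir <- withr::local_tempdir()
  ts <- random_roi_ts(T = 20, N = 10, seed = 42, tr = 2.5, group = "case",
                      id = "subj_07")
  path <- file.path(dir, "subj_07.tsv")
  write_roi_timeseries(ts, path)
  back <- read_roi_timeseries(path)
  expect_identical(back$values, ts$values)
  expect_identical(back$tr_seconds, 2.5)
  expect_identical(back$subject_id, "subj_07")
  expect_identical(back$group, "case")
})

test_that("reader rejects bad cells, missing TR and ambiguous orientation", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x.tsv")
  writeLines(c("1\t2", "3\tfoo", "5\t6"), path)
  jsonlite::write_json(list(tr_seconds = 2, subject_id = "x",
                            group = "case"),
                       file.path(dir, "x.json"), auto_unbox = TRUE)
  expect_error(read_roi_timeseries(path), class = "dfcp_parse_error")

  write_roi_timeseries(random_roi_ts(), file.path(dir, "y.tsv"))
  jsonlite::write_json(list(subject_id = "y", group = "case"),
                       file.path(dir, "y.json"), auto_unbox = TRUE)
  expect_error(read_roi_timeseries(file.path(dir, "y.tsv")),
               class = "dfcp_metadata_error")

  # square matrix without declared orientation is ambiguous
  sq <- random_roi_ts(T = 8, N = 8, seed = 2)
  write_roi_timeseries(sq, file.path(dir, "sq.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "sq.json"),
                              simplifyVector = TRUE)
  meta$orientation <- NULL
  jsonlite::write_json(meta, file.path(dir, "sq.json"), auto_unbox = TRUE)
  expect_error(read_roi_timeseries(file.path(dir, "sq.tsv")),
               class = "dfcp_metadata_error")
})

test_that("declared roi_by_time orientation transposes on read", {
  dir <- withr::local_tempdir()
  ts <- random_roi_ts(T = 12, N = 4, seed = 3)
  path <- file.path(dir, "t.tsv")
  write.table(t(ts$values), path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(tr_seconds = 2, subject_id = "t",
                            group = "control",
                            orientation = "roi_by_time"),
                       file.path(dir, "t.json"), auto_unbox = TRUE)
  expect_equal(read_roi_timeseries(path)$values, ts$values)
})

test_that("feature table writing round-trips and validates shapes", {
  dir <- withr::local_tempdir()
  mk <- function(id, group, K = 3, N = 0, seed = 1) {
    set.seed(seed)
    r <- abs(rnorm(K)); r <- r / sum(r)
    structure(list(ratios = r, mean_betas = rnorm(K),
                   sfc_strength = if (N > 0) abs(rnorm(N)),
                   subject_id = id, group = group),
              class = "dfcp_features")
  }
  path <- file.path(dir, "feat.tsv")
  write_features(list(mk("a", "case", seed = 1), mk("b", "control",
                                                    seed = 2)), path)
  df <- read_features(path)
  expect_equal(names(df),
               c("subject_id", "group", paste0("ratio_", 1:3),
                 paste0("mbeta_", 1:3)))
  expect_equal(nrow(df), 2L)

  # round-trip exactness on many random vectors with an sFC block
  vecs <- lapply(1:50, function(i)
    mk(sprintf("s%02d", i), if (i %% 2) "case" else "control",
       K = 4, N = 6, seed = i))
  write_features(vecs, path)
  df <- read_features(path)
  expect_equal(unname(as.matrix(df[, -(1:2)])),
               unname(do.call(rbind, lapply(vecs, function(v)
                 c(v$ratios, v$mean_betas, v$sfc_strength)))),
               tolerance = 1e-12)

  # mixed dimensionality refused; empty collection gives header only
  expect_error(write_features(list(mk("a", "case", K = 3),
                                   mk("b", "case", K = 4)), path),
               class = "dfcp_shape_error")
  write_features(list(), path)
  expect_equal(readLines(path), "subject_id\tgroup")
})

test_that("cohort write/read reproduces every subject", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(synthetic_spec(n_subjects_per_group = 2,
                                        n_timepoints = 40, seed = 9))
  manifest <- write_cohort(sim, dir)
  back <- read_cohort(manifest)
  expect_length(back, 4L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$values, sim$cohort[[i]]$values,
                 tolerance = 1e-12)
    expect_identical(back[[i]]$group, sim$cohort[[i]]$group)
  }
})
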