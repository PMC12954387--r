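test_that("recording construction validates its invariants", {
  d <- matrix(rnorm(8), 2, 4)
  r <- recording(d, 250, ez_mask = c(TRUE, FALSE))
  expect_s3_class(r, "seeg_recording")
  expect_equal(duration_s(r), 4 / 250)
  d_bad <- d; d_bad[1, 2] <- NaN
  expect_error(recording(d_bad, 250), "NaN")
  expect_error(recording(d, -1), "positive")
  expect_error(recording(d, 250, ez_mask = c(TRUE, FALSE, TRUE)), "ez_mask")
  expect_error(recording(matrix(1, 1, 10), 250), "2 channels")
})

test_that("delimited round-trip reproduces the recording exactly", {
  r <- noise_recording(nc = 4, nt = 100, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(r, path)
  r2 <- read_recording(path)
  expect_equal(r2$data, r$data)
  expect_equal(r2$fs, r$fs)
  expect_equal(r2$ez_mask, r$ez_mask)
  expect_equal(r2$condition, r$condition)
  expect_equal(r2$channel_ids, r$channel_ids)
})

test_that("sidecar channel exclusion drops channels without reordering", {
  r <- noise_recording(nc = 5, nt = 50, seed = 4,
                       ez = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(r, path)
  cat("exclude=ch2\n", file = paste0(path, ".meta"), append = TRUE)
  r2 <- read_recording(path)
  expect_equal(n_channels(r2), 4L)
  expect_equal(r2$channel_ids, r$channel_ids[-2])
  expect_equal(r2$data, r$data[-2, ])
  expect_equal(r2$ez_mask, r$ez_mask[-2])
})

test_that("EDF write-read round-trip preserves signals to quantization error", {
  r <- noise_recording(nc = 3, nt = 500, fs = 250, seed = 9)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(r, path)
  edf <- read_edf(path)
  expect_equal(edf$fs, 250)
  expect_equal(dim(edf$data), dim(r$data))
  expect_equal(edf$channel_ids, r$channel_ids)
  # 16-bit quantization over the per-channel range
  qstep <- (apply(r$data, 1, max) - apply(r$data, 1, min)) / 65535
  expect_true(all(abs(edf$data - r$data) <= qstep + 0.02 * max(qstep)))
  # via read_recording with a sidecar for masks
  writeLines(c("ez_mask=1,0,0", "condition=pMED", "subject_id=s1"),
             paste0(path, ".meta"))
  r3 <- read_recording(path)
  expect_equal(r3$ez_mask, c(TRUE, FALSE, FALSE))
  expect_equal(r3$condition, "pMED")
})

test_that("metrics table round-trips bit-exactly and rejects bad input", {
  tb <- metrics_table(subject_id = c("a", "a"), condition = c("rest", "pMED"),
                      band = "alpha", region = "EZ", metric = "strength",
                      value = c(pi, exp(-12.3456789)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(tb, path)
  expect_identical(read_metrics(path)$value, tb$value)
  expect_length(readLines(path), 3L)  # header + 2 rows
  expect_error(write_metrics(tb[0, ], path), "empty")
  expect_error(metrics_table(subject_id = c("a", "a"), condition = "rest",
                             band = "alpha", region = "EZ",
                             metric = "strength", value = c(1, 2)),
               "duplicate")
  expect_error(metrics_table(subject_id = "a", condition = "rest",
                             band = "alpha", region = "EZ",
                             metric = "strength", value = NaN), "finite")
})

test_that("analysis_config enforces band and parameter invariants", {
  expect_error(analysis_config(bands = list(a = c(4, 2))), "increasing")
  expect_error(analysis_config(bands = list(a = c(1, 5), b = c(4, 8))),
               "disjoint")
  expect_error(analysis_config(window_threshold = 1), "window_threshold")
  expect_silent(analysis_config(window_threshold = -1))
  expect_error(analysis_config(n_bootstrap = 0), "n_bootstrap")
})

test_that("connectivity matrices and simulated segments round-trip through CSV", {
  rec <- noise_recording(nc = 4, nt = 5000, seed = 17)
  adj <- static_adjacency(rec, "alpha", analysis_config(epoch_length_s = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity(adj, path)
  W2 <- read_connectivity(path)
  expect_equal(unname(W2), unname(adj$weights), tolerance = 1e-12)
  expect_equal(rownames(W2), adj$channel_ids)

  seg <- simulate_segment(cohort_spec(n_subjects = 1, n_ez = 2, n_nez = 4,
                                      duration_s = 4, seed = 3),
                          "rest", seed = 5)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_segment(seg, p2)
  back <- read_recording(p2)
  expect_equal(back$data, seg$recording$data)
  truth <- utils::read.csv(paste0(p2, ".truth.csv"))$state
  expect_identical(as.integer(truth), seg$truth$states)
})
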