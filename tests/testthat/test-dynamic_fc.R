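# build an iac_tensor-shaped object from a pairs x time matrix
make_tensor <- function(pairs, nc, fs = 250, condition = "rest") {
  structure(list(pairs = pairs, pair_index = metaseeg:::pair_index(nc),
                 missing = rep(FALSE, nrow(pairs)), n_channels = nc,
                 band = "test", fs = fs, condition = condition,
                 subject_id = "fix", channel_ids = paste0("ch", seq_len(nc)),
                 ez_mask = rep(FALSE, nc)), class = "iac_tensor")
}

test_that("IAC time mean reproduces the static orthogonalized envelope correlation", {
  for (s in 1:3) {
    rec <- noise_recording(nc = 5, nt = 15000, fs = 250, seed = 40 + s)
    sig <- bandpass(rec, "alpha")
    ten <- iac_tensor(sig)
    expect_lt(max(abs(static_envelope_correlation(sig) - iac_time_mean(ten))),
              1e-9)
    expect_equal(unname(diag(iac_slice(ten, 100))), rep(0, 5))
    expect_equal(iac_slice(ten, 100), t(iac_slice(ten, 100)))
  }
})

test_that("IAC of independent channels has near-zero time mean", {
  vals <- sapply(1:15, function(s) {
    rec <- noise_recording(nc = 2, nt = 15000, fs = 250, seed = 300 + s)
    iac_time_mean(iac_tensor(rec, "theta"))[1, 2]
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("windowing handles stability limit cases", {
  nc <- 4
  cfg <- analysis_config(min_window_samples = 25L)
  # constant tensor: a single window spans everything
  const <- make_tensor(matrix(rep(c(0.3, -0.1, 0.5, 0.2, -0.4, 0.1), 400),
                              6, 400), nc)
  wp <- datadriven_windows(const, cfg)
  expect_equal(nrow(wp$windows), 1L)
  expect_equal(wp$windows$length, 400L)
  # threshold -1: nothing ever breaks
  set.seed(2)
  noisy <- make_tensor(matrix(rnorm(6 * 400), 6, 400), nc)
  wp2 <- datadriven_windows(noisy, analysis_config(window_threshold = -1))
  expect_equal(nrow(wp2$windows), 1L)
})

test_that("windows are exhaustive, non-overlapping and mean-consistent", {
  set.seed(3)
  X <- matrix(rnorm(10 * 2000), 10, 2000)
  ten <- make_tensor(X, 5)
  cfg <- analysis_config(window_threshold = 0.3, min_window_samples = 50L)
  wp <- datadriven_windows(ten, cfg)
  expect_equal(wp$windows$start[1], 0L)
  expect_equal(wp$windows$end[nrow(wp$windows)], 2000L)
  expect_identical(wp$windows$start[-1], wp$windows$end[-nrow(wp$windows)])
  expect_true(all(wp$windows$length >= 50L))
  # duration-weighted mean of window means equals the tensor time mean
  wm <- wp$means %*% (wp$windows$length / 2000)
  expect_equal(as.vector(wm), rowMeans(X), tolerance = 1e-12)
})

test_that("a planted regime switch produces a window boundary near it", {
  set.seed(4)
  p <- 45
  a <- rnorm(p); b <- rnorm(p)
  X <- cbind(matrix(rep(a, 700), p) + rnorm(p * 700, sd = 0.05),
             matrix(rep(b, 500), p) + rnorm(p * 500, sd = 0.05))
  ten <- make_tensor(X, 10)
  cfg <- analysis_config(window_threshold = 0.5, min_window_samples = 50L)
  wp <- datadriven_windows(ten, cfg)
  boundaries <- wp$windows$start[-1]
  expect_true(any(abs(boundaries - 700) <= 50))
})

test_that("recurrence plots are valid and reflect window similarity", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  rp <- recurrence_plot(m)
  expect_true(all(rp$C == 1))
  v <- c(1, 2, 3, 4, 5, 6)
  m2 <- cbind(v, rev(v), v)
  rp2 <- recurrence_plot(m2)
  expect_equal(rp2$C, t(rp2$C))
  expect_equal(unname(diag(rp2$C)), rep(1, 3))
  expect_equal(rp2$C[1, 2], -1)
  expect_equal(rp2$C[1, 3], 1)
  expect_error(recurrence_plot(m[, 1, drop = FALSE]), "at least 2 windows")
})

test_that("signed Louvain matches exhaustive modularity maximization on small graphs", {
  all_partitions <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (p in all_partitions(n - 1)) {
      for (c in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, c)
    }
    out
  }
  set.seed(11)
  for (i in 1:6) {
    n <- sample(5:7, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- runif(n * (n - 1) / 2, -1, 1)
    A <- A + t(A)
    res <- metaseeg:::cpp_louvain_signed(A, 50L, 17L + i)
    best <- max(vapply(all_partitions(n), function(p)
      oracle_signed_modularity(A, p), numeric(1)))
    # reported modularity is exactly the signed modularity of the partition
    expect_equal(res$modularity,
                 oracle_signed_modularity(A, res$membership),
                 tolerance = 1e-12)
    # and the heuristic lands at (or extremely near) the exhaustive optimum
    expect_gte(res$modularity, best - 0.02)
  }
})

test_that("two perfect anti-correlated blocks give exactly two meta-states", {
  set.seed(5)
  base <- rnorm(21)
  means <- cbind(base, base + 1e-9, -base, base, -base, -base)
  lens <- rep(100L, 6)
  part <- structure(list(
    sample_window = rep(1:6, each = 100),
    windows = data.frame(start = seq(0, 500, by = 100),
                         end = seq(100, 600, by = 100), length = lens),
    means = means, missing = rep(FALSE, 21),
    pair_index = metaseeg:::pair_index(7), n_channels = 7, fs = 250,
    band = "test", condition = "rest", subject_id = "fix"),
    class = "window_partition")
  model <- detect_meta_states(part, analysis_config(), seed = 1)
  expect_equal(model$K, 2L)
  expect_equal(length(unique(model$window_labels[c(1, 2, 4)])), 1L)
  expect_equal(length(unique(model$window_labels[c(3, 5, 6)])), 1L)
  expect_true(model$window_labels[1] != model$window_labels[3])
})

test_that("TAS assignment picks the best-correlated state with ties to low index", {
  nc <- 6
  np <- nc * (nc - 1) / 2
  set.seed(6)
  topo <- matrix(rnorm(np * 3), np, 3)
  model <- structure(list(topographies = topo, K = 3L,
                          missing = rep(FALSE, np),
                          pair_index = metaseeg:::pair_index(nc),
                          n_channels = nc), class = "meta_state_model")
  X <- cbind(topo[, 2], topo[, 3], topo[, 1], rep(1, np))
  ten <- make_tensor(X, nc)
  tas <- assign_tas(ten, model)
  expect_equal(tas[1:3], c(2L, 3L, 1L))
  expect_equal(tas[4], 1L)   # constant sample: all correlations equal -> state 1
})

test_that("dwell time is the mean run length in seconds", {
  expect_equal(dwell_time(c(1, 1, 1, 2, 2, 2), 250), 3 / 250)
  expect_equal(dwell_time(rep(4L, 100), 250), 100 / 250)
  expect_equal(dwell_time(rep(c(1L, 2L), 50), 250), 1 / 250)
})

test_that("LZ76 complexity matches manual parses and the brute-force oracle", {
  expect_equal(tas_complexity(rep(1L, 6)), 2L)     # a | aaaaa
  expect_equal(tas_complexity(1L), 1L)
  # all binary strings of length 1..9 against the independent oracle
  for (len in 1:9) {
    for (code in 0:(2^len - 1)) {
      s <- as.integer(intToBits(code))[1:len] + 1L
      expect_equal(tas_complexity(s), oracle_lz76(s),
                   info = paste("len", len, "code", code))
    }
  }
  # random sequences beat periodic ones of the same length
  set.seed(9)
  cmp <- replicate(20, {
    rnd <- sample(1:2, 64, replace = TRUE)
    tas_complexity(rnd) > tas_complexity(rep(c(1L, 2L), 32))
  })
  expect_true(all(cmp))
})

test_that("dwell and complexity are invariant under symbol relabeling", {
  set.seed(10)
  s <- sample(1:3, 400, replace = TRUE)
  relab <- c(3L, 1L, 2L)[s]
  expect_equal(dwell_time(s, 250), dwell_time(relab, 250))
  expect_equal(tas_complexity(s), tas_complexity(relab))
})

test_that("NEZ reanalysis equals the global analysis when no channel is EZ", {
  spec <- cohort_spec(n_subjects = 1, n_ez = 2, n_nez = 6,
                      dynamic_bands = "beta2", seed = 21)
  segs <- lapply(simulate_cohort(spec)[[1]]$segments, `[[`, "recording")
  segs_noez <- lapply(segs, function(s) {
    recording(s$data, s$fs, s$channel_ids, rep(FALSE, 8), s$condition,
              s$subject_id)
  })
  cfg <- analysis_config(seed = 3)
  glob <- dfc_subject(segs_noez, "beta2", cfg, region = "global", seed = 5)
  nez <- dfc_subject(segs_noez, "beta2", cfg, region = "NEZ", seed = 5)
  expect_identical(glob$dwell, nez$dwell)
  expect_identical(glob$lzc, nez$lzc)
  # removing EZ channels never changes sampling rate or duration
  sub <- subset_channels(segs$rest, !segs$rest$ez_mask)
  expect_equal(sub$fs, segs$rest$fs)
  expect_equal(n_samples(sub), n_samples(segs$rest))
  expect_error(dfc_subject(lapply(segs, function(s) {
    recording(s$data, s$fs, s$channel_ids, rep(TRUE, 8), s$condition,
              s$subject_id)
  }), "beta2", cfg, region = "NEZ"), "NEZ")
})
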