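test_that("same seed reproduces a bit-identical segment and cohort", {
  spec <- tiny_cohort_spec()
  a <- simulate_segment(spec, "pMED", seed = 77)
  b <- simulate_segment(spec, "pMED", seed = 77)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$states, b$truth$states)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1[[2]]$segments$pMS$recording$data,
                   c2[[2]]$segments$pMS$recording$data)
})

test_that("a cohort has three consistent segments per subject", {
  spec <- tiny_cohort_spec(n_subjects = 2)
  cohort <- simulate_cohort(spec)
  expect_length(cohort, 2L)
  for (subj in cohort) {
    expect_named(subj$segments, c("rest", "pMED", "pMS"))
    masks <- lapply(subj$segments, function(s) s$recording$ez_mask)
    expect_identical(masks$rest, masks$pMED)
    expect_identical(masks$rest, masks$pMS)
    expect_equal(n_samples(subj$segments$rest$recording),
                 spec$fs * spec$duration_s)
    expect_equal(length(subj$segments$rest$truth$states),
                 spec$fs * spec$duration_s)
  }
})

test_that("uncoupled channels have near-zero envelope correlations", {
  spec <- cohort_spec(n_subjects = 1, n_ez = 2, n_nez = 4,
                      dynamic_bands = character(), static_rho = 0,
                      n_states = c(rest = 1, pMED = 1, pMS = 1),
                      dwell_s = c(rest = 1, pMED = 1, pMS = 1), seed = 2)
  vals <- unlist(lapply(1:10, function(s) {
    seg <- simulate_segment(spec, "rest", seed = 100 + s)
    sig <- bandpass(seg$recording, "alpha")
    W <- static_envelope_correlation(sig)
    W[upper.tri(W)]
  }))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("a strongly coupled pair shows higher connectivity than uncoupled pairs", {
  nc <- 6
  S <- diag(nc); S[3, 4] <- S[4, 3] <- 0.9
  spec <- cohort_spec(n_subjects = 1, n_ez = 2, n_nez = 4,
                      dynamic_bands = "beta2", static_rho = 0, rho = 0.9,
                      n_states = c(rest = 1, pMED = 1, pMS = 1),
                      dwell_s = c(rest = 1, pMED = 1, pMS = 1),
                      state_coupling = list(S), seed = 2)
  seg <- simulate_segment(spec, "rest", seed = 31)
  W <- abs(static_envelope_correlation(bandpass(seg$recording, "beta2")))
  coupled <- W[3, 4]
  others <- W[upper.tri(W)]
  others <- others[others != coupled]
  expect_gt(coupled, max(others))
})

test_that("planted dwell parameter controls ground-truth run lengths", {
  spec_fast <- cohort_spec(n_subjects = 1, n_ez = 2, n_nez = 6,
                           dwell_s = c(rest = 0.5, pMED = 0.5, pMS = 0.5),
                           seed = 3)
  spec_slow <- cohort_spec(n_subjects = 1, n_ez = 2, n_nez = 6,
                           dwell_s = c(rest = 2, pMED = 2, pMS = 2),
                           seed = 3)
  run_mean <- function(spec) {
    mean(unlist(lapply(1:8, function(s) {
      rle(simulate_segment(spec, "rest", seed = s)$truth$states)$lengths
    })))
  }
  ratio <- run_mean(spec_slow) / run_mean(spec_fast)
  expect_gt(ratio, 4 * 0.85)
  expect_lt(ratio, 4 * 1.15)
})

test_that("non-positive-semidefinite coupling matrices are rejected", {
  S <- diag(4); S[1, 2] <- S[2, 1] <- 0.9; S[1, 3] <- S[3, 1] <- 0.9
  S[2, 3] <- S[3, 2] <- -0.9
  expect_error(
    cohort_spec(n_subjects = 1, n_ez = 2, n_nez = 2,
                state_coupling = list(S), seed = 1),
    "positive semidefinite")
})
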