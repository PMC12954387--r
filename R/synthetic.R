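# Synthetic SEEG cohort generator.
#
# Each channel is a sum over frequency bands of a band-limited noise carrier
# multiplied by a slow amplitude envelope, plus white observation noise.
# Carriers are independent across channels, so all planted connectivity lives
# in the envelopes: envelopes are rectified low-pass Gaussian processes whose
# cross-channel correlation follows the coupling matrix of the currently
# active planted state. States switch as a semi-Markov process with geometric
# dwell, so the planted sequence has a controllable mean dwell time.
# Condition effects are injected only through the dwell / state-count plan and
# through NEZ coupling, never through the EZ labels themselves.

#' Specification of a synthetic SEEG cohort
#'
#' Defaults describe the study conditions the package is validated under:
#' 60-s segments at 250 Hz, 4 EZ + 44 NEZ contacts per subject, piecewise
#' stationary envelope coupling among NEZ channels in the beta2 and gamma
#' bands (three planted states at rest and before major seizures with 0.5-s
#' mean dwell; two slower states with 1.5-s dwell before minor discharges),
#' block coupling strength 0.95, weak uniform baseline coupling 0.2 in all
#' other bands, 7-Hz envelope bandwidth and observation noise SD 0.05.
#'
#' @param n_subjects number of virtual subjects.
#' @param n_ez,n_nez channels inside / outside the epileptogenic zone.
#' @param fs sampling rate (Hz).
#' @param duration_s segment duration (s).
#' @param bands named list of band intervals (Hz).
#' @param dynamic_bands names of bands carrying the planted state dynamics.
#' @param n_states named integer vector: planted states per condition.
#' @param dwell_s named numeric vector: mean dwell (s) per condition.
#' @param rho envelope coupling inside a state's NEZ blocks (0..1).
#' @param static_rho baseline envelope coupling in non-dynamic bands.
#' @param envelope_cutoff_hz low-pass cutoff of the envelope processes.
#' @param noise_sd observation white-noise SD (signal bands have unit
#'   carrier SD).
#' @param state_coupling optional list of per-state coupling matrices
#'   (channels x channels, symmetric, unit diagonal, positive semidefinite);
#'   built automatically from random NEZ block partitions when `NULL`.
#' @param seed master seed of the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 39L, n_ez = 4L, n_nez = 44L,
                        fs = 250, duration_s = 60,
                        bands = default_bands(),
                        dynamic_bands = c("beta2", "gamma"),
                        n_states = c(rest = 3L, pMED = 2L, pMS = 3L),
                        dwell_s = c(rest = 0.5, pMED = 1.5, pMS = 0.5),
                        rho = 0.95, static_rho = 0.2,
                        envelope_cutoff_hz = 7, noise_sd = 0.05,
                        state_coupling = NULL, seed = 1L) {
  conds <- c("rest", "pMED", "pMS")
  if (!all(conds %in% names(n_states)) || !all(conds %in% names(dwell_s))) {
    stopf("n_states and dwell_s must be named for rest, pMED and pMS")
  }
  if (any(n_states < 1L)) stopf("each condition needs K >= 1 planted states")
  if (any(dwell_s <= 0)) stopf("dwell durations must be positive")
  if (rho < 0 || rho > 1) stopf("rho must lie in [0, 1]")
  spec <- structure(list(
    n_subjects = as.integer(n_subjects), n_ez = as.integer(n_ez),
    n_nez = as.integer(n_nez), fs = fs, duration_s = duration_s,
    bands = bands, dynamic_bands = dynamic_bands,
    n_states = n_states[conds], dwell_s = dwell_s[conds],
    rho = rho, static_rho = static_rho,
    envelope_cutoff_hz = envelope_cutoff_hz, noise_sd = noise_sd,
    state_coupling = state_coupling, seed = as.integer(seed)),
    class = "cohort_spec")
  if (is.null(spec$state_coupling)) {
    spec$state_coupling <- make_state_couplings(spec)
  }
  for (S in spec$state_coupling) validate_coupling(S, spec$n_ez + spec$n_nez)
  spec
}

validate_coupling <- function(S, nc) {
  if (!is.matrix(S) || nrow(S) != nc || ncol(S) != nc) {
    stopf("coupling matrix must be %d x %d", nc, nc)
  }
  if (max(abs(S - t(S))) > 1e-12) stopf("coupling matrix must be symmetric")
  if (max(abs(diag(S) - 1)) > 1e-12) stopf("coupling matrix must have unit diagonal")
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) stopf("coupling matrix is not positive semidefinite (min eigenvalue %.3g)", ev)
  invisible(S)
}

# One coupling matrix per planted state: a bipartition of the NEZ channels,
# coupling `rho` within each part, identity elsewhere. The first three states
# use the three balanced pairings of four fixed NEZ quarters (any two of
# which agree on exactly half of the channel pairs, so the topographies are
# maximally distinct); further states use random bipartitions.
make_state_couplings <- function(spec) {
  nc <- spec$n_ez + spec$n_nez
  k_max <- max(spec$n_states)
  nez_idx <- (spec$n_ez + 1L):nc
  out <- vector("list", k_max)
  rs <- restore_rng()
  on.exit(rs())
  set.seed(derive_seed(spec$seed, 7001L))
  quarter <- rep(1:4, length.out = length(nez_idx))
  pairings <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  for (k in seq_len(k_max)) {
    grp <- if (k <= 3L) {
      pairings[[k]][quarter]
    } else {
      sample(rep(1:2, length.out = length(nez_idx)))
    }
    S <- diag(nc)
    for (g in 1:2) {
      idx <- nez_idx[grp == g]
      S[idx, idx] <- spec$rho
    }
    diag(S) <- 1
    out[[k]] <- S
  }
  out
}

# save the RNG state; returns a restorer
restore_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() invisible(NULL)
  }
}

# semi-Markov state sequence: geometric dwell, uniform jump to another state
simulate_state_sequence <- function(k, dwell_s, fs, nt) {
  if (k == 1L) return(rep(1L, nt))
  p <- 1 / (dwell_s * fs)
  s <- integer(nt)
  cur <- sample.int(k, 1L)
  switches <- stats::runif(nt) < p
  for (t in seq_len(nt)) {
    if (t > 1L && switches[t]) {
      cur <- sample(setdiff(seq_len(k), cur), 1L)
    }
    s[t] <- cur
  }
  s
}

# C x T matrix of correlated smooth Gaussian processes with coupling `S`
coupled_envelopes <- function(S, nt, fs, cutoff) {
  nc <- nrow(S)
  L <- tryCatch(chol(S + diag(1e-10, nc)), error = function(e) {
    stopf("coupling matrix is not positive semidefinite")
  })
  Z <- matrix(stats::rnorm(nc * nt), nc, nt)
  G <- crossprod(L, Z)                       # rows now correlated per S
  n <- ceiling(3.3 * fs / cutoff); n <- n + (n %% 2L)
  h <- signal::fir1(n, cutoff / (fs / 2), type = "low")
  G <- zerophase_filter(G, h)
  sds <- apply(G, 1L, stats::sd)
  abs(G / sds)                               # rectified -> nonnegative envelope
}

# C x T band-limited unit-SD noise carriers, independent across channels
band_carriers <- function(edges, nc, nt, fs) {
  X <- matrix(stats::rnorm(nc * nt), nc, nt)
  n <- fir_order(fs, edges[1])
  h <- signal::fir1(n, edges / (fs / 2), type = "pass")
  X <- zerophase_filter(X, h)
  X / apply(X, 1L, stats::sd)
}

#' Simulate one 60-s segment of one condition
#'
#' @param spec a [cohort_spec()].
#' @param condition `"rest"`, `"pMED"` or `"pMS"`.
#' @param seed seed of this segment (derive from the cohort seed for
#'   reproducible cohorts).
#' @param subject_id label stored in the returned recording.
#' @return a list with `recording` (a `seeg_recording`) and `truth` (planted
#'   per-sample state sequence, the state coupling matrices and the dwell
#'   parameter).
#' @export
simulate_segment <- function(spec, condition = c("rest", "pMED", "pMS"),
                             seed = spec$seed, subject_id = "sim") {
  condition <- match.arg(condition)
  rs <- restore_rng()
  on.exit(rs())
  set.seed(seed)
  nc <- spec$n_ez + spec$n_nez
  nt <- as.integer(round(spec$duration_s * spec$fs))
  k <- spec$n_states[[condition]]
  dwell <- spec$dwell_s[[condition]]
  states <- simulate_state_sequence(k, dwell, spec$fs, nt)

  S_static <- matrix(spec$static_rho, nc, nc); diag(S_static) <- 1
  validate_coupling(S_static, nc)
  data <- matrix(0, nc, nt)
  nb <- length(spec$bands)
  for (b in names(spec$bands)) {
    carriers <- band_carriers(spec$bands[[b]], nc, nt, spec$fs)
    if (b %in% spec$dynamic_bands) {
      env <- matrix(0, nc, nt)
      for (s in seq_len(k)) {
        Ek <- coupled_envelopes(spec$state_coupling[[s]], nt, spec$fs,
                                spec$envelope_cutoff_hz)
        sel <- states == s
        env[, sel] <- Ek[, sel]
      }
    } else {
      # independent envelope process per band with the static baseline coupling
      env <- coupled_envelopes(S_static, nt, spec$fs, spec$envelope_cutoff_hz)
    }
    data <- data + carriers * env / sqrt(nb)
  }
  data <- data + spec$noise_sd * matrix(stats::rnorm(nc * nt), nc, nt)
  ez <- c(rep(TRUE, spec$n_ez), rep(FALSE, spec$n_nez))
  rec <- recording(data, spec$fs,
                   c(sprintf("EZ%02d", seq_len(spec$n_ez)),
                     sprintf("NEZ%02d", seq_len(spec$n_nez))),
                   ez, condition, subject_id)
  list(recording = rec,
       truth = list(states = states,
                    coupling = spec$state_coupling[seq_len(k)],
                    dwell_s = dwell, n_states = k))
}

#' Simulate a full three-condition cohort
#'
#' Per-subject seeds are derived deterministically from the cohort seed, so
#' the same spec always yields the same cohort. All three segments of one
#' subject share the channel geometry and EZ mask.
#'
#' @param spec a [cohort_spec()].
#' @return a list with one element per subject: `subject_id`, `segments`
#'   (named list of rest / pMED / pMS results of [simulate_segment()]).
#' @export
simulate_cohort <- function(spec) {
  if (spec$n_subjects < 1L) stopf("n_subjects must be >= 1")
  conds <- c("rest", "pMED", "pMS")
  lapply(seq_len(spec$n_subjects), function(i) {
    sid <- sprintf("S%02d", i)
    segs <- lapply(seq_along(conds), function(j) {
      simulate_segment(spec, conds[j], seed = derive_seed(spec$seed, i, j),
                       subject_id = sid)
    })
    names(segs) <- conds
    list(subject_id = sid, segments = segs)
  })
}
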