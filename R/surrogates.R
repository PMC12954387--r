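# Amplitude-adjusted Fourier transform (AAFT) surrogates and surrogate
# normalization of dynamic-connectivity metrics.
#
# AAFT destroys genuine temporal dynamics while retaining each channel's
# amplitude distribution exactly. One shared phase-randomization sequence is
# used for all channels of a recording, which preserves cross-channel linear
# correlations and therefore static functional connectivity; only the
# dynamics become those of a stationary linear process.

#' AAFT surrogate of a recording
#'
#' Per channel: rank-remap the samples onto a Gaussian shape, randomize the
#' Fourier phases with a random sequence shared across all channels, and
#' rank-remap back onto the channel's original amplitude distribution. The
#' sorted values of every surrogate channel equal the sorted original values
#' exactly.
#'
#' @param rec a `seeg_recording`.
#' @param seed seed for the shared phase sequence.
#' @return a `seeg_recording` of the same shape.
#' @export
aaft <- function(rec, seed = 1L) {
  nt <- ncol(rec$data)
  if (nt < 2L) stopf("recording too short for surrogate generation")
  rs <- restore_rng(); on.exit(rs())
  set.seed(seed)
  # shared antisymmetric phase sequence (DC and Nyquist untouched)
  half <- (nt - 1L) %/% 2L
  phi <- stats::runif(half, 0, 2 * pi)
  shift <- rep(0, nt)
  if (half > 0L) {
    shift[2L:(half + 1L)] <- phi
    shift[nt:(nt - half + 1L)] <- -phi
  }
  rot <- exp(1i * shift)
  gauss <- stats::qnorm(seq_len(nt) / (nt + 1))
  surro <- t(apply(rec$data, 1L, function(x) {
    rk <- rank(x, ties.method = "first")
    g <- gauss[rk]                            # Gaussianized copy of x
    gs <- Re(stats::fft(stats::fft(g) * rot, inverse = TRUE)) / nt
    sort(x)[rank(gs, ties.method = "first")]  # back to original amplitudes
  }))
  recording(surro, rec$fs, rec$channel_ids, rec$ez_mask,
            rec$condition, rec$subject_id)
}

#' Normalize a dynamic metric by its surrogate ensemble mean
#'
#' Divides an observed metric by the mean of the values obtained from
#' surrogate recordings. Values close to 1 indicate behaviour attributable to
#' random fluctuations of a stationary linear process with the same static
#' connectivity; the further from 1, the more genuinely dynamic the metric.
#'
#' @param value observed metric value.
#' @param ensemble numeric vector of surrogate metric values.
#' @return `value / mean(ensemble)`.
#' @export
normalize_dfc <- function(value, ensemble) {
  m <- mean(ensemble)
  if (!is.finite(m) || m == 0) stopf("surrogate ensemble mean is zero or undefined")
  value / m
}

#' Surrogate-normalized dynamic metrics of one subject and band
#'
#' Runs the full dynamic pipeline ([dfc_subject()]) on the original segments
#' and on `n_surrogates` AAFT ensembles (each 60-s condition block gets its
#' own independent shared-phase surrogate), then divides the observed dwell
#' time and TAS complexity by the surrogate ensemble means. Meta-states are
#' refitted on every surrogate by default; set
#' `config$refit_surrogate_states = FALSE` to reuse the original states and
#' only reassign samples.
#'
#' @param segments named list of `seeg_recording` objects per condition.
#' @param band band name or interval.
#' @param config an [analysis_config()] (`n_surrogates`, refit flag).
#' @param region `"global"` or `"NEZ"`.
#' @param seed master seed (surrogate streams derived by counter).
#' @return a list with `observed` (the [dfc_subject()] result),
#'   `surrogate_mean` (dwell / lzc matrices: condition x 1), and
#'   `normalized` (per-condition `dwell_norm`, `lzc_norm`).
#' @export
surrogate_normalized_dfc <- function(segments, band,
                                     config = analysis_config(),
                                     region = c("global", "NEZ"),
                                     seed = config$seed) {
  region <- match.arg(region)
  observed <- dfc_subject(segments, band, config, region = region,
                          seed = derive_seed(seed, 1L))
  conds <- names(segments)
  dw <- matrix(NA_real_, config$n_surrogates, length(conds),
               dimnames = list(NULL, conds))
  lz <- dw
  for (s in seq_len(config$n_surrogates)) {
    surro <- lapply(seq_along(segments), function(j) {
      aaft(segments[[j]], seed = derive_seed(seed, 100L + s, j))
    })
    names(surro) <- conds
    if (config$refit_surrogate_states) {
      res <- dfc_subject(surro, band, config, region = region,
                         seed = derive_seed(seed, 200L + s))
      dw[s, ] <- res$dwell
      lz[s, ] <- res$lzc
    } else {
      segs <- surro
      if (region == "NEZ") {
        segs <- lapply(segs, function(x) subset_channels(x, !x$ez_mask))
      }
      tensors <- lapply(segs, iac_tensor, band = band, config = config)
      tas <- lapply(tensors, assign_tas, model = observed$model)
      dw[s, ] <- vapply(tas, dwell_time, numeric(1), fs = segs[[1]]$fs)
      lz[s, ] <- vapply(tas, function(q) as.numeric(tas_complexity(q)), numeric(1))
    }
  }
  list(observed = observed,
       surrogate_dwell = dw, surrogate_lzc = lz,
       normalized = list(
         dwell_norm = vapply(conds, function(cn)
           normalize_dfc(observed$dwell[[cn]], dw[, cn]), numeric(1)),
         lzc_norm = vapply(conds, function(cn)
           normalize_dfc(observed$lzc[[cn]], lz[, cn]), numeric(1))))
}
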