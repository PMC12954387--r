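# Static functional connectivity: pairwise leakage-orthogonalized amplitude
# envelope correlation (AEC).
#
# For a pair (x, y) of band-filtered referential signals, the zero-lag linear
# projection of y onto x is removed before correlating amplitude envelopes,
# which suppresses reference- and volume-conduction-driven spurious coupling.
# Both orthogonalization directions are computed and averaged, since the
# operation is not symmetric.

#' Remove the zero-lag linear projection of one signal onto another
#'
#' Returns `y - (<y, x> / <x, x>) x`, the component of `y` orthogonal to `x`
#' at lag zero.
#'
#' @param x reference signal (not identically zero).
#' @param y signal to orthogonalize.
#' @return numeric vector of the same length with `sum(out * x) == 0`.
#' @export
orthogonalize_pair <- function(x, y) {
  if (length(x) != length(y)) stopf("signals must have equal length")
  xx <- sum(x * x)
  if (xx == 0) stopf("cannot orthogonalize against an all-zero signal")
  y - (sum(y * x) / xx) * x
}

# one direction of the AEC on raw (already filtered) vectors:
# envelope of x vs envelope of (y orthogonalized to x)
aec_direction <- function(x, y) {
  r <- orthogonalize_pair(x, y)
  if (all(abs(r) < .Machine$double.eps * max(1, max(abs(y))))) {
    return(0)  # zero-residual convention (e.g. y == x)
  }
  ex <- as.vector(Mod(analytic_signal(x)))
  er <- as.vector(Mod(analytic_signal(r)))
  if (stats::sd(ex) == 0 || stats::sd(er) == 0) return(NA_real_)
  stats::cor(ex, er)
}

#' Orthogonalized amplitude envelope correlation of one epoch
#'
#' Pearson correlation between the analytic-signal amplitude envelopes of two
#' band-filtered signals, after symmetric pairwise orthogonalization (the two
#' directed estimates are averaged). Degenerate inputs with a constant
#' envelope yield `NA` (flagged missing); an identically zero residual (e.g.
#' `y` equal to `x`) contributes 0 by convention.
#'
#' @param x,y band-filtered signal vectors (one epoch).
#' @return a correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
aec_epoch <- function(x, y) {
  d <- c(aec_direction(x, y), aec_direction(y, x))
  if (all(is.na(d))) return(NA_real_)
  mean(d, na.rm = TRUE)
}

# Envelope of the orthogonalized pair over the full segment, from the complex
# analytic matrix A and the filtered gram matrix G: analytic() is linear, so
# the analytic signal of y - c x is A_y - c A_x.
ortho_envelopes <- function(A, G, i, j) {
  cji <- G[j, i] / G[i, i]
  Mod(A[j, ] - cji * A[i, ])
}

# epoch-wise Pearson correlation, averaged over epochs; NA epochs (constant
# envelope) are excluded from the average
epoch_mean_cor <- function(ea, eb, epochs) {
  vals <- vapply(epochs, function(idx) {
    a <- ea[idx]; b <- eb[idx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# core AEC machinery shared by the epoch-averaged static adjacency and the
# whole-segment envelope correlation used by the dynamic layer
aec_matrix <- function(sig, epochs, rectify = "abs") {
  F <- sig$filtered
  nc <- nrow(F)
  A <- analytic_signal(F)
  G <- tcrossprod(F)
  W <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1L)) {
    ei <- Mod(A[i, ])
    for (j in (i + 1L):nc) {
      if (G[i, i] == 0 || G[j, j] == 0) { W[i, j] <- NA_real_; next }
      ej <- Mod(A[j, ])
      rj <- ortho_envelopes(A, G, i, j)   # env of j orthogonalized to i
      ri <- ortho_envelopes(A, G, j, i)   # env of i orthogonalized to j
      zero_rj <- all(abs(A[j, ] - (G[j, i] / G[i, i]) * A[i, ]) < 1e-12)
      zero_ri <- all(abs(A[i, ] - (G[i, j] / G[j, j]) * A[j, ]) < 1e-12)
      d1 <- if (zero_rj) 0 else epoch_mean_cor(ei, rj, epochs)
      d2 <- if (zero_ri) 0 else epoch_mean_cor(ej, ri, epochs)
      d <- c(d1, d2)
      W[i, j] <- if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
    }
  }
  W <- W + t(W)
  diag(W) <- 0
  if (rectify == "abs") W <- abs(W)
  W
}

#' Static connectivity adjacency matrix of one segment and band
#'
#' Band-filters the recording, orthogonalizes each channel pair in both
#' directions over the whole segment, extracts amplitude envelopes, splits
#' them into non-overlapping epochs (12 x 5 s for a 60-s segment at the
#' defaults) and averages the per-epoch envelope correlations. The averaged
#' correlation is rectified (absolute value) by default so that downstream
#' graph metrics operate on nonnegative weights; set `rectify = "none"` in
#' the config to keep signed values.
#'
#' @param x a `seeg_recording`, or a `band_signals` object (in which case
#'   `band` is ignored).
#' @param band band name or `c(low, high)` interval in Hz.
#' @param config an [analysis_config()].
#' @return an object of class `connectivity_matrix`: list with `weights`
#'   (symmetric, zero diagonal), `band`, `condition`, `subject_id`,
#'   `channel_ids`, `ez_mask`.
#' @export
static_adjacency <- function(x, band = NULL, config = analysis_config()) {
  sig <- if (inherits(x, "band_signals")) x else bandpass(x, band, config$bands)
  epochs <- epoch_indices(sig, config$epoch_length_s)
  W <- aec_matrix(sig, epochs, rectify = config$rectify)
  if (anyNA(W)) {
    msg_stage("static_adjacency: ", sum(is.na(W[upper.tri(W)])),
              " pair(s) flagged missing (constant envelope)")
  }
  structure(list(weights = W, band = sig$band, condition = sig$condition,
                 subject_id = sig$subject_id, channel_ids = sig$channel_ids,
                 ez_mask = sig$ez_mask), class = "connectivity_matrix")
}

#' Whole-segment orthogonalized envelope correlation
#'
#' The non-epoch-averaged, non-rectified counterpart of [static_adjacency()]:
#' one Pearson correlation per pair over the full segment. This is the static
#' quantity that the time average of the instantaneous amplitude correlation
#' tensor reproduces exactly.
#'
#' @param sig a `band_signals` object.
#' @return symmetric numeric matrix with zero diagonal (signed values).
#' @export
static_envelope_correlation <- function(sig) {
  aec_matrix(sig, list(seq_len(ncol(sig$filtered))), rectify = "none")
}
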