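# Resampling, zero-phase band-pass filtering and analytic-envelope extraction.
#
# Filters are windowed-sinc FIR designs (signal::fir1, Hamming window) applied
# forward and backward, which squares the magnitude response (>= 40 dB
# stopband becomes >= 80 dB) and cancels the phase. Because delta-band filters
# at 250 Hz need thousands of taps, the forward-backward pass is executed as a
# single FFT convolution with the filter's autocorrelation, which is
# mathematically identical to filtfilt with zero initial conditions.

# FIR length: >= 3 cycles of the band's low edge and a transition width of
# 25% of the low edge (Hamming main-lobe factor 3.3).
fir_order <- function(fs, low) {
  trans <- 0.25 * low
  n <- max(ceiling(3.3 * fs / trans), ceiling(3 * fs / low))
  n + (n %% 2L)  # even order -> odd, symmetric tap count
}

# zero-phase filtering of the rows of `x` with FIR taps `h`
zerophase_filter <- function(x, h) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  g <- signal::conv(h, rev(h))  # forward pass then time-reversed pass
  nt <- ncol(x); lg <- length(g); half <- (lg - 1L) %/% 2L
  nfft <- stats::nextn(nt + lg - 1L, 2L)
  G <- stats::fft(c(g, rep(0, nfft - lg)))
  out <- t(apply(x, 1L, function(row) {
    X <- stats::fft(c(row, rep(0, nfft - nt)))
    full <- Re(stats::fft(X * G, inverse = TRUE)) / nfft
    full[(half + 1L):(half + nt)]
  }))
  dimnames(out) <- dimnames(x)
  out
}

# analytic signal (FFT Hilbert transform) of the rows of `x`
analytic_signal <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  nt <- ncol(x)
  mult <- rep(0, nt)
  if (nt %% 2L == 0L) {
    mult[1L] <- 1; mult[nt / 2L + 1L] <- 1
    mult[2L:(nt / 2L)] <- 2
  } else {
    mult[1L] <- 1
    mult[2L:((nt + 1L) / 2L)] <- 2
  }
  out <- t(apply(x, 1L, function(row) {
    stats::fft(stats::fft(row) * mult, inverse = TRUE) / nt
  }))
  dimnames(out) <- dimnames(x)
  out
}

#' Resample a recording to a lower sampling rate
#'
#' Decimation applies a zero-phase FIR anti-aliasing filter (cutoff 90% of
#' the target Nyquist) before keeping every `fs/target_fs`-th sample.
#' Non-integer ratios fall back to polyphase resampling
#' ([signal::resample()]). Upsampling is refused.
#'
#' @param rec a `seeg_recording`.
#' @param target_fs target sampling rate in Hz (`<= rec$fs`).
#' @return a `seeg_recording` at `target_fs`; duration is preserved to within
#'   one sample.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs) stopf("no upsampling: target %g Hz > %g Hz", target_fs, rec$fs)
  if (target_fs == rec$fs) return(rec)
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    d <- as.integer(round(ratio))
    cutoff <- 0.9 * target_fs / 2
    trans <- 0.2 * target_fs / 2
    n <- ceiling(3.3 * rec$fs / trans); n <- n + (n %% 2L)
    h <- signal::fir1(n, cutoff / (rec$fs / 2), type = "low")
    filt <- zerophase_filter(rec$data, h)
    data <- filt[, seq(1L, ncol(filt), by = d), drop = FALSE]
  } else {
    q <- NULL
    for (den in 1:1000) {
      p <- target_fs * den / rec$fs
      if (abs(p - round(p)) < 1e-9) { q <- den; break }
    }
    if (is.null(q)) stopf("fs ratio %g is not rational enough to resample", ratio)
    p <- as.integer(round(target_fs * q / rec$fs))
    data <- t(apply(rec$data, 1L, function(row) signal::resample(row, p, q)))
  }
  recording(data, target_fs, rec$channel_ids, rec$ez_mask,
            rec$condition, rec$subject_id)
}

#' Band-pass filter a recording and extract amplitude envelopes
#'
#' Zero-phase (forward-backward) windowed-sinc FIR filtering into one
#' frequency band, followed by the amplitude envelope as the magnitude of the
#' analytic signal of the whole trace (computing the envelope before epoching
#' avoids per-epoch transients).
#'
#' @param rec a `seeg_recording`.
#' @param band `c(low, high)` in Hz, or the name of a band in `bands`.
#' @param bands named list of band definitions (default [default_bands()]).
#' @return an object of class `band_signals`: list with `band`, `edges`,
#'   `filtered` and `envelope` (channels x samples), `fs`, plus the source
#'   recording's masks and labels. The first and last second are flagged in
#'   `edge_samples` as potentially affected by filter edge effects.
#' @export
bandpass <- function(rec, band, bands = default_bands()) {
  if (is.character(band)) {
    band_name <- band
    if (is.null(bands[[band]])) stopf("unknown band '%s'", band)
    edges <- bands[[band]]
  } else {
    band_name <- paste0(band[1], "-", band[2], "Hz")
    edges <- band
  }
  nyq <- rec$fs / 2
  if (edges[1] <= 0 || edges[2] >= nyq) {
    stopf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz", edges[1], edges[2], nyq)
  }
  n <- fir_order(rec$fs, edges[1])
  h <- signal::fir1(n, edges / nyq, type = "pass")
  filtered <- zerophase_filter(rec$data, h)
  env <- Mod(analytic_signal(filtered))
  dimnames(env) <- dimnames(filtered)
  structure(list(
    band = band_name, edges = edges, filtered = filtered, envelope = env,
    fs = rec$fs, channel_ids = rec$channel_ids, ez_mask = rec$ez_mask,
    condition = rec$condition, subject_id = rec$subject_id,
    edge_samples = min(as.integer(rec$fs), ncol(filtered) %/% 2L)),
    class = "band_signals")
}

#' Partition band signals into non-overlapping epochs
#'
#' Splits the segment into contiguous, exhaustive, non-overlapping epochs of
#' `epoch_length_s` seconds. The epoch length must divide the segment length
#' exactly; partial epochs are refused.
#'
#' @param sig a `band_signals` object (or a plain channels x samples matrix
#'   with attribute-free splitting).
#' @param epoch_length_s epoch duration in seconds (matrix input: in columns).
#' @param fs sampling rate, required for matrix input.
#' @return a list of column-index vectors, one per epoch, in temporal order.
#' @export
epoch_indices <- function(sig, epoch_length_s, fs = NULL) {
  if (inherits(sig, "band_signals")) {
    nt <- ncol(sig$filtered); fs <- sig$fs
  } else {
    nt <- ncol(sig)
    if (is.null(fs)) stopf("`fs` is required for matrix input")
  }
  len <- epoch_length_s * fs
  if (abs(len - round(len)) > 1e-9) stopf("epoch length %g s is not a whole number of samples", epoch_length_s)
  len <- as.integer(round(len))
  if (nt %% len != 0L) {
    stopf("epoch length %g s (%d samples) does not divide the %d-sample segment",
          epoch_length_s, len, nt)
  }
  split(seq_len(nt), rep(seq_len(nt %/% len), each = len))
}
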