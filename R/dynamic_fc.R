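# Dynamic functional connectivity: instantaneous amplitude correlation (IAC)
# tensors, recurrence plots over data-driven windows, meta-state detection by
# signed-modularity Louvain community detection, temporal activation
# sequences (TAS), dwell time and Lempel-Ziv complexity.

# canonical pair ordering shared by the whole dynamic layer: column-major
# upper triangle, i.e. (1,2), (1,3), (2,3), (1,4), ...
pair_index <- function(nc) {
  which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
}

#' Instantaneous amplitude correlation tensor of one segment and band
#'
#' For each channel pair, both signals are orthogonalized against each other
#' (both directions, zero-lag), amplitude envelopes are z-scored over the
#' whole segment, and the per-sample product of the two z-scores is averaged
#' over the two orthogonalization directions. The time mean of each pair's
#' series equals the whole-segment orthogonalized envelope correlation of
#' that pair exactly.
#'
#' @param x a `seeg_recording` or `band_signals` object.
#' @param band band name or interval (ignored for `band_signals` input).
#' @param config an [analysis_config()].
#' @return an object of class `iac_tensor`: `pairs` is a (n_pairs x
#'   n_samples) matrix in canonical upper-triangle order, `pair_index` maps
#'   rows to channel pairs, `missing` flags pairs with a constant envelope.
#' @export
iac_tensor <- function(x, band = NULL, config = analysis_config()) {
  sig <- if (inherits(x, "band_signals")) x else bandpass(x, band, config$bands)
  F <- sig$filtered
  nc <- nrow(F); nt <- ncol(F)
  A <- analytic_signal(F)
  G <- tcrossprod(F)
  pidx <- pair_index(nc)
  np <- nrow(pidx)
  # orthogonalization in both directions, z-scored envelopes, averaged
  # product — done in compiled code (analytic() is linear, so the residual's
  # analytic signal is A_y - c A_x)
  pairs <- cpp_iac_pairs(Re(A), Im(A), G)
  missing <- !is.finite(pairs[, 1L])
  pairs[missing, ] <- NA_real_
  structure(list(pairs = pairs, pair_index = pidx, missing = missing,
                 n_channels = nc, band = sig$band, fs = sig$fs,
                 condition = sig$condition, subject_id = sig$subject_id,
                 channel_ids = sig$channel_ids, ez_mask = sig$ez_mask),
            class = "iac_tensor")
}

#' Extract one temporal slice of an IAC tensor as a matrix
#'
#' @param tensor an `iac_tensor`.
#' @param t sample index (1-based).
#' @return symmetric channels x channels matrix with zero diagonal.
#' @export
iac_slice <- function(tensor, t) {
  nc <- tensor$n_channels
  M <- matrix(0, nc, nc)
  M[upper.tri(M)] <- tensor$pairs[, t]
  M <- M + t(M)
  dimnames(M) <- list(tensor$channel_ids, tensor$channel_ids)
  M
}

#' Time-mean connectivity matrix of an IAC tensor
#' @param tensor an `iac_tensor`.
#' @return symmetric channels x channels matrix (missing pairs `NA`).
#' @export
iac_time_mean <- function(tensor) {
  v <- rowMeans(tensor$pairs)
  nc <- tensor$n_channels
  M <- matrix(0, nc, nc)
  M[upper.tri(M)] <- v
  M + t(M)
}

#' Data-driven stable-connectivity windows
#'
#' Greedy segmentation of the IAC tensor: the current window grows while the
#' Spearman correlation between the incoming sample's connectivity vector and
#' the running window mean stays at or above `config$window_threshold`; when
#' the correlation drops the window is closed (provided it has at least
#' `config$min_window_samples` samples) and a new one starts. Window
#' boundaries are kept out of the first and last half second of the segment,
#' where filter edge effects live. Pairs flagged missing are excluded from
#' the similarity vectors.
#'
#' @param tensor an `iac_tensor`.
#' @param config an [analysis_config()].
#' @return an object of class `window_partition`: `sample_window` (1-based
#'   window id per sample), `windows` (data.frame with 0-based half-open
#'   `start`, `end` and `length`), `means` (pairs x windows mean
#'   connectivity, `NA` rows for missing pairs).
#' @export
datadriven_windows <- function(tensor, config = analysis_config()) {
  if (config$window_threshold < -1 || config$window_threshold >= 1) {
    stopf("window_threshold must lie in [-1, 1)")
  }
  ok <- !tensor$missing
  if (sum(ok) < 3L) stopf("too few valid pairs for windowing")
  X <- tensor$pairs[ok, , drop = FALSE]
  nt <- ncol(X)
  if (nt < 2L * config$min_window_samples) {
    stopf("segment too short: need at least 2 * min_window_samples samples")
  }
  guard <- as.integer(round(tensor$fs / 2))
  ids <- cpp_greedy_windows(X, config$window_threshold,
                            config$min_window_samples, guard)
  nw <- max(ids)
  means <- matrix(NA_real_, nrow(tensor$pairs), nw)
  lens <- integer(nw)
  for (w in seq_len(nw)) {
    sel <- ids == w
    lens[w] <- sum(sel)
    means[ok, w] <- rowMeans(X[, sel, drop = FALSE])
  }
  starts <- c(0L, cumsum(lens)[-nw])
  structure(list(sample_window = ids,
                 windows = data.frame(start = starts, end = starts + lens,
                                      length = lens),
                 means = means, missing = tensor$missing,
                 pair_index = tensor$pair_index,
                 n_channels = tensor$n_channels, fs = tensor$fs,
                 band = tensor$band, condition = tensor$condition,
                 subject_id = tensor$subject_id), class = "window_partition")
}

#' Temporally-constrained recurrence plot of a window partition
#'
#' Spearman correlation between the vectorized mean connectivity matrices of
#' every pair of windows.
#'
#' @param partition a `window_partition` (or a pairs x windows matrix of
#'   window means).
#' @return an object of class `recurrence_plot` with symmetric unit-diagonal
#'   matrix `C` in `[-1, 1]`.
#' @export
recurrence_plot <- function(partition) {
  means <- if (inherits(partition, "window_partition")) partition$means else partition
  means <- means[stats::complete.cases(means), , drop = FALSE]
  if (ncol(means) < 2L) stopf("a recurrence plot needs at least 2 windows")
  C <- stats::cor(means, method = "spearman")
  diag(C) <- 1
  structure(list(C = C, n_windows = ncol(means)), class = "recurrence_plot")
}

#' Detect recurrent connectivity meta-states across the three conditions
#'
#' Concatenates the data-driven windows of the per-condition IAC tensors of
#' one subject, builds the recurrence plot over all windows, treats it as a
#' signed weighted graph (windows = nodes, Spearman correlations = edges,
#' negative values allowed) and maximizes signed modularity — positive and
#' negative weights contribute separate null terms — with a Louvain
#' algorithm, without presetting the number of communities. Each community is
#' a meta-state; its topography is the duration-weighted mean connectivity of
#' its member windows.
#'
#' @param partitions named list of `window_partition` objects (one per
#'   condition, typically rest / pMED / pMS); a single partition is also
#'   accepted.
#' @param config an [analysis_config()] (Louvain restarts).
#' @param seed seed for the restart streams.
#' @return an object of class `meta_state_model`: `topographies` (pairs x K),
#'   `window_labels`, `window_condition`, `window_lengths`, `modularity`,
#'   `K`, `rp` (the concatenated recurrence plot), `missing` pair mask.
#' @export
detect_meta_states <- function(partitions, config = analysis_config(),
                               seed = config$seed) {
  if (inherits(partitions, "window_partition")) partitions <- list(partitions)
  means <- do.call(cbind, lapply(partitions, `[[`, "means"))
  lens <- unlist(lapply(partitions, function(p) p$windows$length), use.names = FALSE)
  wcond <- unlist(lapply(seq_along(partitions), function(i) {
    p <- partitions[[i]]
    rep(p$condition %||% names(partitions)[i] %||% as.character(i),
        nrow(p$windows))
  }), use.names = FALSE)
  missing <- Reduce(`|`, lapply(partitions, `[[`, "missing"))
  if (ncol(means) < 2L) stopf("meta-state detection needs more than one window")
  rp <- recurrence_plot(means[!missing, , drop = FALSE])
  A <- rp$C
  diag(A) <- 0  # self-similarity carries no community information
  res <- cpp_louvain_signed(A, config$louvain_restarts, derive_seed(seed, 424L))
  labels <- res$membership
  K <- max(labels)
  topo <- matrix(NA_real_, nrow(means), K)
  for (k in seq_len(K)) {
    sel <- labels == k
    w <- lens[sel] / sum(lens[sel])
    topo[, k] <- as.vector(means[, sel, drop = FALSE] %*% w)
  }
  structure(list(topographies = topo, window_labels = labels,
                 window_condition = wcond, window_lengths = lens,
                 modularity = res$modularity, K = K, rp = rp,
                 missing = missing,
                 pair_index = partitions[[1]]$pair_index,
                 n_channels = partitions[[1]]$n_channels,
                 subject_id = partitions[[1]]$subject_id,
                 band = partitions[[1]]$band), class = "meta_state_model")
}

#' Assign each sample its dominant meta-state
#'
#' The temporal activation sequence (TAS): for every original sample of the
#' IAC tensor, the meta-state whose topography has the highest Spearman
#' correlation with the sample's connectivity vector. Exact ties resolve to
#' the lowest state index.
#'
#' @param tensor an `iac_tensor` (one condition).
#' @param model a `meta_state_model` fitted on the same subject and band.
#' @return integer vector of state symbols in `1..model$K`.
#' @export
assign_tas <- function(tensor, model) {
  ok <- !(tensor$missing | model$missing)
  if (sum(ok) < 3L) stopf("too few valid pairs for state assignment")
  cpp_assign_states(tensor$pairs[ok, , drop = FALSE],
                    model$topographies[ok, , drop = FALSE])
}

#' Mean dwell time of a symbolic state sequence
#'
#' Mean length of the maximal constant runs, in seconds. Computed per
#' condition block: never concatenate conditions before calling this.
#'
#' @param tas integer (or factor) state sequence.
#' @param fs sampling rate (Hz).
#' @return mean dwell time in seconds.
#' @export
dwell_time <- function(tas, fs) {
  if (!length(tas)) stopf("empty state sequence")
  mean(rle(as.integer(tas))$lengths) / fs
}

#' Lempel-Ziv complexity of a symbolic state sequence
#'
#' LZ76 phrase count: the number of distinct phrases found by scanning the
#' sequence and opening a new phrase whenever the current substring cannot be
#' copied from the previous history. The sequence is used as-is (it is
#' already symbolic, no binarization).
#'
#' @param tas integer (or factor) state sequence.
#' @return integer phrase count.
#' @export
tas_complexity <- function(tas) {
  if (!length(tas)) stopf("empty state sequence")
  cpp_lz76(as.integer(as.factor(tas)))
}

#' Full dynamic-connectivity analysis of one subject and band
#'
#' Runs the dynamic pipeline for one subject: band-pass, IAC tensor and
#' data-driven windows per condition, meta-states on the concatenated
#' windows, then per-condition TAS, dwell time and TAS complexity (dwell and
#' complexity are computed inside each condition block, never across block
#' boundaries). With `region = "NEZ"` the epileptogenic-zone contacts are
#' removed first and the whole process is repeated on the remaining network.
#'
#' @param segments named list of `seeg_recording` objects (rest, pMED, pMS —
#'   any nonempty subset).
#' @param band band name or interval.
#' @param config an [analysis_config()].
#' @param region `"global"` (all contacts) or `"NEZ"` (EZ contacts removed).
#' @param seed seed for the community-detection restarts.
#' @return a list with `model` (the `meta_state_model`), and per-condition
#'   `tas`, `dwell` (s) and `lzc`.
#' @export
dfc_subject <- function(segments, band, config = analysis_config(),
                        region = c("global", "NEZ"), seed = config$seed) {
  region <- match.arg(region)
  if (region == "NEZ") {
    nnez <- sum(!segments[[1]]$ez_mask)
    if (nnez < 2L) stopf("NEZ reanalysis needs at least 2 NEZ channels (have %d)", nnez)
    segments <- lapply(segments, function(s) subset_channels(s, !s$ez_mask))
  }
  tensors <- lapply(segments, function(s) {
    msg_stage(s$subject_id, " ", s$condition, " ", band, " ", region, ": IAC")
    iac_tensor(s, band, config)
  })
  partitions <- lapply(tensors, datadriven_windows, config = config)
  model <- detect_meta_states(partitions, config, seed = seed)
  tas <- lapply(tensors, assign_tas, model = model)
  list(model = model,
       tas = tas,
       dwell = vapply(tas, dwell_time, numeric(1), fs = segments[[1]]$fs),
       lzc = vapply(tas, function(s) as.numeric(tas_complexity(s)), numeric(1)))
}
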