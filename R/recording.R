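#' Construct a multichannel intracerebral recording
#'
#' The basic data container of the package: a channels x samples matrix of
#' referential-montage intracerebral EEG (microvolts) together with its
#' sampling rate, channel labels, epileptogenic-zone (EZ) membership mask and
#' the experimental condition the segment was taken from (interictal rest, the
#' 60 s preceding a minor electrical discharge, or the 60 s preceding a major
#' seizure).
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_ids character vector of channel labels (default "ch1"...).
#' @param ez_mask logical vector, `TRUE` for contacts inside the EZ.
#' @param condition one of `"rest"`, `"pMED"`, `"pMS"` (or `NA`).
#' @param subject_id subject label.
#' @return an object of class `seeg_recording`.
#' @export
recording <- function(data, fs, channel_ids = NULL, ez_mask = NULL,
                      condition = NA_character_, subject_id = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric matrix (channels x samples)")
  }
  if (nrow(data) < 2L) stopf("a recording needs at least 2 channels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stopf("`fs` must be a single positive number")
  }
  if (any(!is.finite(data))) stopf("recording contains NaN/Inf values")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data)) {
    stopf("channel_ids length (%d) does not match channel count (%d)",
          length(channel_ids), nrow(data))
  }
  if (is.null(ez_mask)) ez_mask <- rep(FALSE, nrow(data))
  if (!is.logical(ez_mask) || length(ez_mask) != nrow(data)) {
    stopf("ez_mask must be logical with one entry per channel (got %d, need %d)",
          length(ez_mask), nrow(data))
  }
  if (!is.na(condition)) condition <- match.arg(condition, c("rest", "pMED", "pMS"))
  rownames(data) <- channel_ids
  structure(
    list(data = data, fs = fs, channel_ids = as.character(channel_ids),
         ez_mask = ez_mask, condition = condition,
         subject_id = as.character(subject_id)),
    class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("<seeg_recording> subject %s, condition %s\n", x$subject_id,
              x$condition))
  cat(sprintf("  %d channels (%d EZ) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), sum(x$ez_mask), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Number of channels / samples and duration of a recording
#' @param rec a `seeg_recording`.
#' @return integer or numeric scalar.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_channels
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Keep a subset of channels of a recording
#'
#' Subsetting never reorders the surviving channels: they keep the order they
#' had in the source recording.
#'
#' @param rec a `seeg_recording`.
#' @param keep logical mask or integer indices of channels to keep.
#' @return a `seeg_recording` with the selected channels.
#' @export
subset_channels <- function(rec, keep) {
  if (is.logical(keep)) keep <- which(keep)
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) < 2L) stopf("channel subset must keep at least 2 channels")
  recording(rec$data[keep, , drop = FALSE], rec$fs,
            rec$channel_ids[keep], rec$ez_mask[keep],
            rec$condition, rec$subject_id)
}

#' Read a recording from disk
#'
#' Supports two on-disk formats: European Data Format (`.edf`) for
#' clinical-style input, and a plain comma-delimited channels x samples matrix
#' (no header) accompanied by a sidecar key-value annotation file. The sidecar
#' (`<path>.meta` by default) holds `fs`, `ez_mask` (comma-separated 0/1),
#' `condition`, `subject_id` and optionally `exclude` (comma-separated channel
#' labels or 1-based indices to drop). For EDF input `fs` comes from the file
#' header and the sidecar supplies the remaining annotations.
#'
#' @param path path to a `.edf` file or a delimited matrix file.
#' @param meta optional path to the sidecar annotation file (default
#'   `paste0(path, ".meta")` if it exists).
#' @return a validated `seeg_recording`; excluded channels are absent and the
#'   surviving channels keep the file order.
#' @export
read_recording <- function(path, meta = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(meta) && file.exists(paste0(path, ".meta"))) {
    meta <- paste0(path, ".meta")
  }
  ann <- if (is.null(meta)) list() else read_sidecar(meta)
  is_edf <- grepl("\\.edf$", path, ignore.case = TRUE)
  if (is_edf) {
    edf <- read_edf(path)
    data <- edf$data
    fs <- edf$fs
    channel_ids <- edf$channel_ids
  } else {
    data <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(data) <- NULL
    if (!is.numeric(data)) stopf("malformed delimited matrix in %s", path)
    if (is.null(ann$fs)) stopf("sidecar must supply `fs` for delimited input")
    fs <- as.numeric(ann$fs)
    channel_ids <- if (!is.null(ann$channel_ids)) {
      strsplit(ann$channel_ids, ",")[[1]]
    } else paste0("ch", seq_len(nrow(data)))
  }
  ez_mask <- if (!is.null(ann$ez_mask)) {
    as.integer(strsplit(ann$ez_mask, ",")[[1]]) == 1L
  } else rep(FALSE, nrow(data))
  if (length(ez_mask) != nrow(data)) {
    stopf("ez_mask length (%d) does not match channel count (%d)",
          length(ez_mask), nrow(data))
  }
  rec <- recording(data, fs, channel_ids, ez_mask,
                   ann$condition %||% NA_character_,
                   ann$subject_id %||% NA_character_)
  if (!is.null(ann$exclude)) {
    excl <- trimws(strsplit(ann$exclude, ",")[[1]])
    idx <- suppressWarnings(as.integer(excl))
    drop <- if (all(!is.na(idx))) idx else match(excl, rec$channel_ids)
    drop <- drop[!is.na(drop)]
    if (length(drop)) rec <- subset_channels(rec, setdiff(seq_len(nrow(rec$data)), drop))
  }
  rec
}

#' Write a recording in the delimited-matrix format
#'
#' Writes the channels x samples matrix as comma-separated values (no header)
#' and the annotations to a `<path>.meta` sidecar so that
#' `read_recording(path)` reproduces the recording.
#'
#' @param rec a `seeg_recording`.
#' @param path destination path for the matrix file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  lines <- apply(rec$data, 1L, function(row) paste(sprintf("%.17g", row), collapse = ","))
  writeLines(lines, path)
  side <- c(
    sprintf("fs=%.17g", rec$fs),
    sprintf("channel_ids=%s", paste(rec$channel_ids, collapse = ",")),
    sprintf("ez_mask=%s", paste(as.integer(rec$ez_mask), collapse = ",")),
    sprintf("condition=%s", rec$condition),
    sprintf("subject_id=%s", rec$subject_id))
  writeLines(side, paste0(path, ".meta"))
  invisible(path)
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(p) trimws(p[2]))
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. Defaults reproduce the
#' standard analysis: six canonical frequency bands below the 125 Hz Nyquist
#' of 250 Hz data, 5-s epochs (12 per 60-s segment), 100 bootstrap
#' node-downsampling repetitions to 4 EZ + 44 NEZ nodes, 100 surrogates, and
#' the data-driven windowing parameters of the dynamic stage.
#'
#' @param bands named list of `c(low, high)` frequency intervals in Hz.
#' @param epoch_length_s epoch duration (s) for static connectivity.
#' @param n_bootstrap node-downsampling repetitions.
#' @param n_surrogates surrogate count for metric normalization.
#' @param target_nodes named vector `c(ez = ..., nez = ...)`: downsample sizes.
#' @param window_threshold Spearman similarity cutoff of the data-driven
#'   windowing (a window grows while incoming samples correlate at least this
#'   much with the running window mean).
#' @param min_window_samples minimum window length in samples.
#' @param rectify `"abs"` to use absolute AEC values as graph weights,
#'   `"none"` to keep signed values.
#' @param edge_length `"inv"` for shortest-path edge lengths `1/w`,
#'   `"one_minus"` for `1 - w`.
#' @param louvain_restarts random restarts of the community detection.
#' @param refit_surrogate_states logical; refit meta-states on each surrogate
#'   (the default) or reuse the original states.
#' @param alpha significance level of the statistical layer.
#' @param seed master random seed.
#' @return an object of class `seeg_config` (a list).
#' @export
analysis_config <- function(bands = default_bands(),
                            epoch_length_s = 5,
                            n_bootstrap = 100L,
                            n_surrogates = 100L,
                            target_nodes = c(ez = 4L, nez = 44L),
                            window_threshold = 0.35,
                            min_window_samples = 88L,
                            rectify = c("abs", "none"),
                            edge_length = c("inv", "one_minus"),
                            louvain_restarts = 20L,
                            refit_surrogate_states = TRUE,
                            alpha = 0.05,
                            seed = 1L) {
  rectify <- match.arg(rectify)
  edge_length <- match.arg(edge_length)
  if (!length(bands) || is.null(names(bands))) stopf("`bands` must be a named list")
  for (b in names(bands)) {
    e <- bands[[b]]
    if (length(e) != 2L || e[1] <= 0 || e[2] <= e[1]) {
      stopf("band `%s` must be a positive increasing interval", b)
    }
  }
  ord <- order(vapply(bands, `[`, numeric(1), 1L))
  lo <- vapply(bands[ord], `[`, numeric(1), 1L)
  hi <- vapply(bands[ord], `[`, numeric(1), 2L)
  if (any(hi[-length(hi)] > lo[-1] + 1e-9)) stopf("bands must be disjoint")
  if (n_bootstrap < 1L) stopf("n_bootstrap must be >= 1")
  if (n_surrogates < 1L) stopf("n_surrogates must be >= 1")
  if (window_threshold < -1 || window_threshold >= 1) {
    stopf("window_threshold must lie in [-1, 1)")
  }
  structure(list(
    bands = bands, epoch_length_s = epoch_length_s,
    n_bootstrap = as.integer(n_bootstrap),
    n_surrogates = as.integer(n_surrogates),
    target_nodes = c(ez = as.integer(target_nodes[["ez"]]),
                     nez = as.integer(target_nodes[["nez"]])),
    window_threshold = window_threshold,
    min_window_samples = as.integer(min_window_samples),
    rectify = rectify, edge_length = edge_length,
    louvain_restarts = as.integer(louvain_restarts),
    refit_surrogate_states = isTRUE(refit_surrogate_states),
    alpha = alpha, seed = as.integer(seed)), class = "seeg_config")
}

#' The six canonical analysis bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta1 13-19, beta2 19-30 and
#' gamma 30-48 Hz.
#'
#' @return named list of frequency intervals (Hz).
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta1 = c(13, 19), beta2 = c(19, 30), gamma = c(30, 48))
}

#' Build a long-format metrics table
#'
#' The interchange format between the connectivity layers and the statistics
#' layer: one row per (subject, condition, band, region, metric) with a finite
#' value. `region` is `"global"`, `"EZ"` or `"NEZ"`.
#'
#' @param subject_id,condition,band,region,metric,value vectors of equal
#'   length (recycled by `data.frame`).
#' @return a `data.frame` with those six columns.
#' @export
metrics_table <- function(subject_id = character(), condition = character(),
                          band = character(), region = character(),
                          metric = character(), value = numeric()) {
  df <- data.frame(subject_id = subject_id, condition = condition,
                   band = band, region = region, metric = metric,
                   value = value, stringsAsFactors = FALSE)
  validate_metrics_table(df)
}

validate_metrics_table <- function(df) {
  need <- c("subject_id", "condition", "band", "region", "metric", "value")
  if (!all(need %in% names(df))) {
    stopf("metrics table must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(df)) {
    key <- do.call(paste, c(df[need[1:5]], sep = "\r"))
    if (anyDuplicated(key)) stopf("metrics table has duplicate key tuples")
    if (any(!is.finite(df$value))) stopf("metrics table values must be finite")
  }
  df
}

#' Write / read a metrics table as CSV
#'
#' Values are printed at full double precision (`%.17g`) so a write-read
#' round-trip is bit-exact.
#'
#' @param table a metrics table (see [metrics_table()]).
#' @param path destination CSV path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns the table.
#' @export
write_metrics <- function(table, path) {
  table <- validate_metrics_table(table)
  if (!nrow(table)) stopf("refusing to write an empty metrics table")
  out <- table
  out$value <- sprintf("%.17g", out$value)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stopf("cannot open %s for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$value <- as.numeric(df$value)
  validate_metrics_table(df)
}
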