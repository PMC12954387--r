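# CSV serialization of the mid-pipeline objects: dense labeled connectivity
# matrices, meta-state models (topography matrices + symbol sequences), and
# synthetic segments with their planted ground truth.

#' Write / read a connectivity matrix as labeled dense CSV
#'
#' @param M a `connectivity_matrix`.
#' @param path destination CSV path (channel labels as header and first
#'   column).
#' @return `write_connectivity()` returns `path` invisibly;
#'   `read_connectivity()` returns a plain symmetric matrix with dimnames.
#' @export
write_connectivity <- function(M, path) {
  W <- M$weights
  dimnames(W) <- list(M$channel_ids, M$channel_ids)
  utils::write.csv(W, path)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Serialize a meta-state model to a directory
#'
#' Writes one dense CSV per state topography (as a channels x channels
#' matrix, `state<k>.csv`), the window labels (`windows.csv`: condition,
#' length, state), and — when provided — the per-condition temporal
#' activation sequences, one symbol per line (`tas_<condition>.txt`).
#'
#' @param model a `meta_state_model`.
#' @param dir destination directory (created if needed).
#' @param tas optional named list of per-condition TAS vectors.
#' @return `dir`, invisibly.
#' @export
write_meta_state_model <- function(model, dir, tas = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nc <- model$n_channels
  for (k in seq_len(model$K)) {
    M <- matrix(0, nc, nc)
    M[model$pair_index] <- model$topographies[, k]
    M <- M + t(M)
    utils::write.csv(M, file.path(dir, sprintf("state%d.csv", k)),
                     row.names = FALSE)
  }
  utils::write.csv(
    data.frame(condition = model$window_condition,
               length = model$window_lengths,
               state = model$window_labels),
    file.path(dir, "windows.csv"), row.names = FALSE)
  for (cond in names(tas)) {
    writeLines(as.character(tas[[cond]]),
               file.path(dir, sprintf("tas_%s.txt", cond)))
  }
  invisible(dir)
}

#' Write a simulated segment with its planted ground truth
#'
#' The recording goes to the delimited core format (matrix + sidecar); the
#' planted per-sample state sequence goes to `<path>.truth.csv` with one
#' symbol per row.
#'
#' @param segment a result of [simulate_segment()].
#' @param path destination path for the recording matrix.
#' @return `path`, invisibly.
#' @export
write_segment <- function(segment, path) {
  write_recording(segment$recording, path)
  utils::write.csv(data.frame(state = segment$truth$states),
                   paste0(path, ".truth.csv"), row.names = FALSE)
  invisible(path)
}
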