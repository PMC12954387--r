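#' @useDynLib metaseeg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Derive a reproducible child seed from a master seed
#'
#' Combines a master seed with one or more integer counters into a new seed in
#' `[1, 2^31 - 2]` using a small multiplicative hash. Used throughout the
#' package so that per-subject, per-repetition and per-surrogate random streams
#' are decoupled from each other while remaining a pure function of the master
#' seed.
#'
#' @param seed master seed (single integer).
#' @param ... integer counters (e.g. subject index, repetition index).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in as.numeric(c(...))) {
    h <- (h * 48271 + k + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

msg_stage <- function(...) {
  if (isTRUE(getOption("metaseeg.verbose", FALSE))) {
    message("[metaseeg] ", ...)
  }
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# upper-triangle vector (column-major, i < j) of a square matrix
ut_vec <- function(M) M[upper.tri(M)]

# rebuild a symmetric zero-diagonal matrix from its upper-triangle vector
ut_unvec <- function(v, n) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- v
  M + t(M)
}
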