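# Minimal European Data Format (EDF) support: 16-bit integer samples,
# standard 256-byte header blocks, one sampling rate shared by all signals.
# Covers the clinical-style input path; the companion writer exists so tests
# can build EDF files programmatically (EDF is binary and never stored as a
# fixture).

read_ascii_field <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a (minimal) EDF file
#'
#' Parses the standard EDF header and the 16-bit little-endian sample records,
#' rescales digital values to physical units, and returns the signals as a
#' channels x samples matrix. All signals must share one sampling rate.
#'
#' @param path path to the `.edf` file.
#' @return a list with `data` (channels x samples, physical units), `fs` (Hz)
#'   and `channel_ids`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii_field(con, 8L)
  if (version != "0") stopf("unsupported EDF version field: '%s'", version)
  invisible(readBin(con, "raw", 160L))            # patient + recording id
  invisible(readBin(con, "raw", 16L))             # start date + time
  header_bytes <- as.integer(read_ascii_field(con, 8L))
  invisible(readBin(con, "raw", 44L))             # reserved
  n_records <- as.integer(read_ascii_field(con, 8L))
  record_dur <- as.numeric(read_ascii_field(con, 8L))
  ns <- as.integer(read_ascii_field(con, 4L))
  if (is.na(ns) || ns < 1L) stopf("malformed EDF header (signal count)")
  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii_field(con, w), character(1))
  labels <- fld(16L)
  invisible(fld(80L))                             # transducer
  invisible(fld(8L))                              # physical dimension
  phys_min <- as.numeric(fld(8L))
  phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L))
  dig_max <- as.numeric(fld(8L))
  invisible(fld(80L))                             # prefiltering
  spr <- as.integer(fld(8L))                      # samples per record
  invisible(fld(32L))                             # reserved
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr))) ||
      is.na(header_bytes) || is.na(n_records) || is.na(record_dur)) {
    stopf("malformed EDF header in %s", path)
  }
  if (length(unique(spr)) != 1L) {
    stopf("EDF signals with mixed sampling rates are not supported")
  }
  if (n_records < 0L) stopf("EDF files with unknown record count are not supported")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[1], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(raw) != spr[1]) stopf("truncated EDF data in %s", path)
      cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
      data[s, cols] <- (raw - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  list(data = data, fs = spr[1] / record_dur, channel_ids = labels)
}

#' Write a (minimal) EDF file
#'
#' Quantizes each channel to the 16-bit digital range over its physical
#' min/max and writes standard EDF records. One-second data records are used,
#' so `n_samples(rec)` must be divisible by `rec$fs`.
#'
#' @param rec a `seeg_recording`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  ns <- nrow(data)
  spr <- as.integer(rec$fs)
  if (spr != rec$fs || ncol(data) %% spr != 0L) {
    stopf("write_edf needs an integer fs dividing the sample count")
  }
  n_records <- ncol(data) %/% spr
  # round the physical range outward to the header's 0.01 resolution and
  # quantize against the rounded values, so file and header agree exactly
  phys_min <- floor(apply(data, 1L, min) * 100) / 100
  phys_max <- ceiling(apply(data, 1L, max) * 100) / 100
  flat <- phys_max - phys_min < 0.01
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- rep(-32768, ns); dig_max <- rep(32767, ns)
  pad <- function(x, w) {
    s <- substr(format(x, justify = "left"), 1L, w)
    sprintf("%-*s", w, s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wrt <- function(s) writeBin(charToRaw(s), con)
  wrt(pad("0", 8L))
  wrt(pad("X X X X", 80L)); wrt(pad("Startdate X X X X", 80L))
  wrt(pad("01.01.00", 8L)); wrt(pad("00.00.00", 8L))
  wrt(pad(256L * (1L + ns), 8L)); wrt(pad("", 44L))
  wrt(pad(n_records, 8L)); wrt(pad("1", 8L)); wrt(pad(ns, 4L))
  for (lab in rec$channel_ids) wrt(pad(lab, 16L))
  for (i in seq_len(ns)) wrt(pad("", 80L))
  for (i in seq_len(ns)) wrt(pad("uV", 8L))
  for (v in phys_min) wrt(pad(sprintf("%.2f", v), 8L))
  for (v in phys_max) wrt(pad(sprintf("%.2f", v), 8L))
  for (v in dig_min) wrt(pad(v, 8L))
  for (v in dig_max) wrt(pad(v, 8L))
  for (i in seq_len(ns)) wrt(pad("", 80L))
  for (i in seq_len(ns)) wrt(pad(spr, 8L))
  for (i in seq_len(ns)) wrt(pad("", 32L))
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((data[s, cols] - phys_min[s]) * gain[s] + dig_min[s])
      writeBin(as.integer(pmin(pmax(dig, dig_min[s]), dig_max[s])), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}
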