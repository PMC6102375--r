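# Recording I/O: a minimal EDF (European Data Format, 16-bit) writer and
# reader sufficient for single-channel chronic LFP, and a raw-binary
# (little-endian float32) format with a YAML sidecar header. Amplitudes
# are converted to microvolts on read.

pad_field <- function(value, width) {
  s <- as.character(value)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  sprintf(sprintf("%%-%ds", width), s)
}

# Format a number into an EDF fixed-width ASCII field without truncating
# digits: drop precision until it fits.
edf_num <- function(value, width) {
  if (value == round(value) && nchar(format(round(value))) <= width) {
    return(pad_field(format(round(value)), width))
  }
  for (digits in seq(width, 1L)) {
    s <- formatC(value, digits = digits, format = "g", flag = "-")
    s <- trimws(s)
    if (nchar(s) <= width) return(pad_field(s, width))
  }
  stop(sprintf("cannot format %g into %d characters", value, width),
       call. = FALSE)
}

#' Write a recording to EDF
#'
#' Writes a single-channel EDF file (16-bit samples, one-second data
#' records). The physical range is set symmetrically to the absolute
#' maximum of the trace, so the amplitude resolution is
#' `max(|x|)/32767`. The trace is zero-padded to a whole number of
#' one-second records; the sampling rate must be a positive integer.
#'
#' @param recording An [lfp_recording()] (amplitudes in microvolts).
#' @param path Output path.
#' @param physical_dimension Unit string written to the header
#'   (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_dimension = "uV") {
  stopifnot(inherits(recording, "lfp_recording"))
  fs <- recording$sampling_rate
  if (fs != round(fs)) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  x <- recording$samples
  scale_out <- switch(physical_dimension,
                      uV = 1, mV = 1e-3, V = 1e-6,
                      stop(sprintf("unsupported physical dimension: %s",
                                   physical_dimension), call. = FALSE))
  x <- x * scale_out
  n_rec <- ceiling(length(x) / fs)
  x <- c(x, numeric(n_rec * fs - length(x)))
  pmax_ <- max(abs(x), 1e-12)
  dig <- as.integer(round(x / pmax_ * 32767))

  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    pad_field("0", 8),
    pad_field(recording$subject_id, 80),
    pad_field("ictalkit synthetic LFP", 80),
    pad_field("01.01.26", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * 2, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(1, 4),
    # one signal's header block
    pad_field("LFP", 16),
    pad_field("twisted wire bipolar", 80),
    pad_field(physical_dimension, 8),
    edf_num(-pmax_, 8),
    edf_num(pmax_, 8),
    edf_num(-32767, 8),
    edf_num(32767, 8),
    pad_field("", 80),
    pad_field(fs, 8),
    pad_field("", 32)
  )
  writeBin(charToRaw(header), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1L):(offset + width)]))
}

#' Read a recording from EDF
#'
#' Parses the EDF header, reads the requested signal, rescales digital
#' values to physical units, and converts amplitudes to microvolts
#' (physical dimensions `uV`, `mV`, and `V` are understood; anything
#' else is a unit-mismatch error).
#'
#' @param path EDF file path.
#' @param channel 1-based signal index (default 1).
#' @return An [lfp_recording()] with the subject identity taken from the
#'   patient field.
#' @export
read_edf <- function(path, channel = 1L) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  head0 <- readBin(con, "raw", 256L)
  if (length(head0) < 256L) {
    stop(sprintf("truncated EDF file: %s", path), call. = FALSE)
  }
  subject_id <- read_edf_field(head0, 8L, 80L)
  n_rec <- as.integer(read_edf_field(head0, 236L, 8L))
  rec_dur <- as.numeric(read_edf_field(head0, 244L, 8L))
  ns <- as.integer(read_edf_field(head0, 252L, 4L))
  if (is.na(ns) || ns < 1L) {
    stop(sprintf("unknown format: %s is not an EDF file", path),
         call. = FALSE)
  }
  if (channel < 1L || channel > ns) {
    stop(sprintf("channel %d out of range (file has %d signals)",
                 channel, ns), call. = FALSE)
  }
  sig <- readBin(con, "raw", 256L * ns)
  if (length(sig) < 256L * ns) {
    stop(sprintf("truncated EDF file: %s", path), call. = FALSE)
  }
  field <- function(width, base) {
    # per-signal header fields are stored field-major across signals
    vapply(seq_len(ns), function(i) {
      read_edf_field(sig, base * ns + (i - 1L) * width, width)
    }, character(1))
  }
  # field base offsets within the signal header block
  phys_dim <- field(8L, 96L)
  phys_min <- as.numeric(field(8L, 104L))
  phys_max <- as.numeric(field(8L, 112L))
  dig_min <- as.numeric(field(8L, 120L))
  dig_max <- as.numeric(field(8L, 128L))
  spr <- as.integer(field(8L, 216L))

  total <- sum(spr)
  data <- readBin(con, "integer", n_rec * total, size = 2L,
                  endian = "little")
  if (length(data) < n_rec * total) {
    stop(sprintf("truncated EDF file: %s", path), call. = FALSE)
  }
  mat_idx <- unlist(lapply(seq_len(n_rec) - 1L, function(r) {
    r * total + sum(spr[seq_len(channel - 1L)]) + seq_len(spr[channel])
  }))
  dig <- data[mat_idx]
  ch <- channel
  phys <- (dig - dig_min[ch]) * (phys_max[ch] - phys_min[ch]) /
    (dig_max[ch] - dig_min[ch]) + phys_min[ch]
  to_uv <- switch(phys_dim[ch],
                  uV = 1, mV = 1e3, V = 1e6,
                  stop(sprintf("unit mismatch: unsupported physical dimension '%s'",
                               phys_dim[ch]), call. = FALSE))
  lfp_recording(phys * to_uv, spr[ch] / rec_dur, subject_id = subject_id)
}

# --------------------------------------------------------------------------
# Raw binary (float32 little-endian) + YAML sidecar header
# --------------------------------------------------------------------------

raw_header_path <- function(path) paste0(path, ".hdr")

#' Write a recording as raw binary with a sidecar header
#'
#' Samples are stored as little-endian float32 in `path`; a YAML sidecar
#' header `path.hdr` records `subject_id`, `sampling_rate`, `n_samples`,
#' `units`, `start_offset`, `dtype`, and `byte_order`.
#'
#' @param recording An [lfp_recording()].
#' @param path Output path for the binary samples.
#' @param units Unit the samples are written in (`"uV"`, `"mV"`, `"V"`).
#' @return `path`, invisibly.
#' @export
write_raw_binary <- function(recording, path, units = "uV") {
  stopifnot(inherits(recording, "lfp_recording"))
  scale_out <- switch(units, uV = 1, mV = 1e-3, V = 1e-6,
                      stop(sprintf("unsupported units: %s", units),
                           call. = FALSE))
  con <- file(path, "wb")
  writeBin(as.numeric(recording$samples * scale_out), con, size = 4L,
           endian = "little")
  close(con)
  yaml::write_yaml(list(
    subject_id = recording$subject_id,
    sampling_rate = recording$sampling_rate,
    n_samples = length(recording$samples),
    units = units,
    start_offset = recording$start_offset,
    dtype = "float32",
    byte_order = "little"
  ), raw_header_path(path))
  invisible(path)
}

#' Read a raw-binary recording
#'
#' @param path Binary samples path; the sidecar header `path.hdr` must
#'   exist.
#' @return An [lfp_recording()] in microvolts.
#' @export
read_raw_binary <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  hdr_path <- raw_header_path(path)
  if (!file.exists(hdr_path)) {
    stop(sprintf("missing sidecar header: %s", hdr_path), call. = FALSE)
  }
  hdr <- yaml::read_yaml(hdr_path)
  needed <- c("sampling_rate", "n_samples", "units")
  if (!all(needed %in% names(hdr))) {
    stop(sprintf("sidecar header %s lacks required fields", hdr_path),
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", hdr$n_samples, size = 4L, endian = "little")
  if (length(x) < hdr$n_samples) {
    stop(sprintf("truncated file: %s", path), call. = FALSE)
  }
  to_uv <- switch(hdr$units, uV = 1, mV = 1e3, V = 1e6,
                  stop(sprintf("unit mismatch: unsupported units '%s'",
                               hdr$units), call. = FALSE))
  lfp_recording(x * to_uv, hdr$sampling_rate,
                subject_id = hdr$subject_id %||% "unknown",
                start_offset = hdr$start_offset %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording, dispatching on format
#'
#' @param path Input path.
#' @param format `"auto"` (by extension: `.edf` -> EDF, otherwise raw
#'   binary), `"edf"`, or `"raw"`.
#' @param channel EDF signal index.
#' @return An [lfp_recording()] in microvolts.
#' @export
read_recording <- function(path, format = c("auto", "edf", "raw"),
                           channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "raw"
  }
  switch(format,
         edf = read_edf(path, channel = channel),
         raw = read_raw_binary(path))
}

#' Write a recording, dispatching on format
#'
#' @param recording An [lfp_recording()].
#' @param path Output path.
#' @param format `"auto"`, `"edf"`, or `"raw"` (as [read_recording()]).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path,
                            format = c("auto", "edf", "raw")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "raw"
  }
  switch(format,
         edf = write_edf(recording, path),
         raw = write_raw_binary(recording, path))
}
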