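# Semiautomated flagging of candidate large behavioral seizures (LBSs):
# FFT bandpass (20-200 Hz) of the raw LFP, envelope via the magnitude of
# the inverse transform, zero-phase Butterworth smoothing, and per-subject
# threshold crossing. Flagged sections are meant for manual review and
# extended-Racine scoring.

#' LBS flagger parameters
#'
#' @param band_low_hz,band_high_hz Passband edges in Hz (defaults 20 and
#'   200); must satisfy `0 < band_low_hz < band_high_hz < sampling_rate/2`.
#' @param smoother_order Butterworth order of the envelope smoother
#'   (default 2; applied forward and backward, so the effective order is
#'   doubled).
#' @param smoother_cutoff_hz Low-pass cutoff of the smoother in Hz
#'   (default 0.1, the normalized 0.1/500 cutoff of the original pipeline
#'   at 1 kHz sampling, expressed in Hz so other sampling rates behave
#'   equivalently).
#' @param threshold_uv Per-subject review threshold in microvolts; `NA`
#'   until set (see [suggest_threshold()]).
#' @param min_flag_gap_s Candidate intervals separated by less than this
#'   many seconds are merged (default 10).
#' @return An object of class `lbs_flag_params`.
#' @export
lbs_flag_params <- function(band_low_hz = 20, band_high_hz = 200,
                            smoother_order = 2, smoother_cutoff_hz = 0.1,
                            threshold_uv = NA_real_, min_flag_gap_s = 10) {
  if (!is.finite(band_low_hz) || band_low_hz <= 0 ||
      !is.finite(band_high_hz) || band_high_hz <= band_low_hz) {
    stop("require 0 < band_low_hz < band_high_hz", call. = FALSE)
  }
  if (!is.finite(smoother_cutoff_hz) || smoother_cutoff_hz <= 0) {
    stop("smoother_cutoff_hz must be positive", call. = FALSE)
  }
  if (!is.finite(smoother_order) || smoother_order < 1 ||
      smoother_order != round(smoother_order)) {
    stop("smoother_order must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      band_low_hz = as.numeric(band_low_hz),
      band_high_hz = as.numeric(band_high_hz),
      smoother_order = as.integer(smoother_order),
      smoother_cutoff_hz = as.numeric(smoother_cutoff_hz),
      threshold_uv = as.numeric(threshold_uv),
      min_flag_gap_s = as.numeric(min_flag_gap_s)
    ),
    class = "lbs_flag_params"
  )
}

#' FFT bandpass envelope of a recording
#'
#' Transforms the trace with a discrete Fourier transform, zeroes
#' coefficients outside the `[band_low_hz, band_high_hz]` passband, and
#' returns the magnitude of the inverse transform.
#'
#' Three spectral-zeroing modes are provided:
#' \describe{
#'   \item{`"analytic"` (default)}{Keeps only positive-frequency in-band
#'     bins (doubled, Hilbert-style), so the magnitude of the complex
#'     inverse transform is the conventional amplitude envelope: for an
#'     in-band sine of amplitude `A` the result is a constant `A`.}
#'   \item{`"symmetric"`}{Zeroes out-of-band bins on both the positive-
#'     and negative-frequency side; the inverse transform is the real
#'     band-limited signal and the envelope its rectification.}
#'   \item{`"printed"`}{Reproduces the original published index
#'     arithmetic literally: bins `1:floor(band_low_hz/fs)` and
#'     `floor(band_high_hz/fs):n` are zeroed, with out-of-range indices
#'     ignored. Because `band/fs` is a frequency divided by a sampling
#'     rate rather than a bin index, both indices collapse to 0 at
#'     typical sampling rates and the mode is a documented no-op (the
#'     envelope is then just `|x|`). The intended bin index is
#'     `floor(f * n / fs)`, which is what the other modes use.}
#' }
#'
#' @param recording An [lfp_recording()].
#' @param params [lbs_flag_params()]; the band must lie inside the
#'   Nyquist frequency.
#' @param mode Spectral-zeroing mode, see Details.
#' @return Numeric envelope trace, same length and rate as the input,
#'   everywhere non-negative, in microvolts.
#' @examples
#' fs <- 1000
#' rec <- lfp_recording(100 * sin(2 * pi * 50 * seq(0, 2, by = 1 / fs)), fs)
#' env <- bandpass_envelope(rec, lbs_flag_params())
#' range(env[500:1500])
#' @export
bandpass_envelope <- function(recording, params = lbs_flag_params(),
                              mode = c("analytic", "symmetric", "printed")) {
  stopifnot(inherits(recording, "lfp_recording"))
  mode <- match.arg(mode)
  fs <- recording$sampling_rate
  if (params$band_high_hz >= fs / 2) {
    stop("passband must lie inside the Nyquist frequency", call. = FALSE)
  }
  x <- recording$samples
  n <- length(x)
  fx <- stats::fft(x)

  if (mode == "printed") {
    i_lo <- floor(params$band_low_hz / fs)
    i_hi <- floor(params$band_high_hz / fs)
    if (i_lo >= 1) fx[seq_len(min(i_lo, n))] <- 0
    if (i_hi >= 1 && i_hi <= n) fx[i_hi:n] <- 0
    return(Mod(stats::fft(fx, inverse = TRUE)) / n)
  }

  k <- seq_len(n) - 1L
  f_signed <- ifelse(k <= n / 2, k, k - n) * fs / n
  in_band_pos <- f_signed >= params$band_low_hz &
    f_signed <= params$band_high_hz

  if (mode == "analytic") {
    fx[!in_band_pos] <- 0
    nyq <- if (n %% 2L == 0L) n / 2 + 1L else NA_integer_
    dbl <- in_band_pos
    if (!is.na(nyq)) dbl[nyq] <- FALSE
    fx[dbl] <- 2 * fx[dbl]
    Mod(stats::fft(fx, inverse = TRUE)) / n
  } else {
    in_band <- abs(f_signed) >= params$band_low_hz &
      abs(f_signed) <= params$band_high_hz
    fx[!in_band] <- 0
    abs(Re(stats::fft(fx, inverse = TRUE)) / n)
  }
}

# Zero-phase IIR filtering with odd-reflection edge padding: forward pass,
# time reversal, second pass, reversal. Padding length defaults to three
# smoother time constants so start-up transients decay inside the pads.
# Each pass is run relative to its first sample, which (with the
# smoother's unity DC gain) makes a constant input map to itself exactly.
filtfilt_padded <- function(filt, x, pad_n) {
  n <- length(x)
  p <- min(pad_n, n - 1L)
  if (p > 0L) {
    head_pad <- 2 * x[1L] - x[(p + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
    xp <- c(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  run <- function(z) signal::filter(filt, z - z[1L]) + z[1L]
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(p + 1L):(p + n)]
}

#' Smooth an envelope with a zero-phase Butterworth low-pass
#'
#' Applies a Butterworth low-pass of order `smoother_order` forward and
#' backward (zero phase, effective order doubled) with cutoff
#' `smoother_cutoff_hz`. Edges are handled with odd-reflection padding of
#' about three filter time constants so that a constant input returns the
#' same constant.
#'
#' @param envelope Numeric envelope trace (from [bandpass_envelope()]).
#' @param params [lbs_flag_params()].
#' @param sampling_rate Sampling rate of the envelope in Hz; the cutoff
#'   must be below the Nyquist frequency.
#' @return Smoothed envelope, same length as the input.
#' @export
smooth_envelope <- function(envelope, params = lbs_flag_params(),
                            sampling_rate = 1000) {
  if (params$smoother_cutoff_hz >= sampling_rate / 2) {
    stop("smoother cutoff must be below the Nyquist frequency",
         call. = FALSE)
  }
  bw <- signal::butter(params$smoother_order,
                       params$smoother_cutoff_hz / (sampling_rate / 2),
                       type = "low")
  pad_n <- round(3 / params$smoother_cutoff_hz * sampling_rate)
  filtfilt_padded(bw, as.numeric(envelope), pad_n)
}

#' Flag candidate LBS intervals
#'
#' Returns the maximal intervals where the smoothed envelope exceeds the
#' per-subject threshold, merging intervals separated by less than
#' `min_flag_gap_s`. Each flagged section is intended for manual review
#' and extended-Racine scoring.
#'
#' @param smoothed Smoothed envelope trace (from [smooth_envelope()]).
#' @param params [lbs_flag_params()] with a positive `threshold_uv`.
#' @param sampling_rate Sampling rate of the envelope in Hz.
#' @return A data frame with columns `start_s`, `end_s` (half-open,
#'   seconds) and `peak_envelope_uv`, sorted and non-overlapping; zero
#'   rows when the envelope never exceeds the threshold.
#' @export
flag_candidates <- function(smoothed, params, sampling_rate = 1000) {
  if (!is.finite(params$threshold_uv) || params$threshold_uv <= 0) {
    stop("threshold_uv must be positive", call. = FALSE)
  }
  above <- smoothed > params$threshold_uv
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_envelope_uv = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  merged <- merge_intervals((starts - 1L) / sampling_rate,
                            ends / sampling_rate,
                            gap = params$min_flag_gap_s)
  peak <- vapply(seq_along(merged$start), function(j) {
    i0 <- floor(merged$start[j] * sampling_rate) + 1L
    i1 <- min(length(smoothed), ceiling(merged$end[j] * sampling_rate))
    max(smoothed[i0:i1])
  }, numeric(1))
  data.frame(start_s = merged$start, end_s = merged$end,
             peak_envelope_uv = peak)
}

#' Suggest a per-subject LBS review threshold
#'
#' The original per-subject thresholds were hand-tuned; this helper
#' proposes `k` times the median of the smoothed envelope, which scales
#' with the trace (multiplying the recording by `c` multiplies the
#' suggestion by `c`) and sits well above seizure-free background while
#' staying far below embedded LBS-band activity.
#'
#' @param recording An [lfp_recording()]; by default at least one hour
#'   long, because the median must be dominated by inter-ictal data.
#' @param params [lbs_flag_params()].
#' @param k Threshold multiple of the median smoothed envelope
#'   (default 5).
#' @param envelope Optional precomputed smoothed envelope (skips the
#'   recording-based computation; `recording` may then be `NULL`).
#' @param allow_short Set `TRUE` to accept recordings shorter than one
#'   hour.
#' @return Suggested threshold in microvolts.
#' @export
suggest_threshold <- function(recording = NULL, params = lbs_flag_params(),
                              k = 5, envelope = NULL, allow_short = FALSE) {
  if (is.null(envelope)) {
    stopifnot(inherits(recording, "lfp_recording"))
    if (!allow_short && lfp_duration(recording) < 3600) {
      stop("recording shorter than 1 h; pass allow_short = TRUE to override",
           call. = FALSE)
    }
    envelope <- smooth_envelope(bandpass_envelope(recording, params),
                                params, recording$sampling_rate)
  }
  med <- stats::median(envelope)
  if (!is.finite(med) || med <= 0) {
    stop("degenerate envelope: median is zero", call. = FALSE)
  }
  k * med
}

#' Run the full LBS flagging pipeline on a recording
#'
#' Convenience wrapper: bandpass envelope, zero-phase smoothing, and
#' threshold flagging. When `params$threshold_uv` is `NA`, a threshold is
#' suggested with [suggest_threshold()].
#'
#' @inheritParams bandpass_envelope
#' @param k Threshold multiple used when no threshold is set.
#' @return A list with `candidates` (see [flag_candidates()]),
#'   `threshold_uv`, and `smoothed` (the smoothed envelope).
#' @export
flag_lbs <- function(recording, params = lbs_flag_params(), k = 5,
                     mode = "analytic") {
  env <- bandpass_envelope(recording, params, mode = mode)
  sm <- smooth_envelope(env, params, recording$sampling_rate)
  if (!is.finite(params$threshold_uv)) {
    params$threshold_uv <- suggest_threshold(params = params, k = k,
                                             envelope = sm)
  }
  list(
    candidates = flag_candidates(sm, params, recording$sampling_rate),
    threshold_uv = params$threshold_uv,
    smoothed = sm
  )
}

#' Write an LBS candidate review queue (CSV)
#'
#' Columns: `subject_id`, `start_s`, `end_s`, `peak_envelope_uv`,
#' `clip_start_s`, `clip_end_s`. The clip window pads each candidate by
#' `clip_pad_s` on both sides (clamped at zero) for human review and
#' Racine scoring.
#'
#' @param candidates Data frame from [flag_candidates()].
#' @param path CSV path.
#' @param subject_id Subject identifier column value.
#' @param clip_pad_s Padding in seconds around each candidate.
#' @return `path`, invisibly.
#' @export
write_candidate_queue <- function(candidates, path, subject_id = "unknown",
                                  clip_pad_s = 15) {
  out <- data.frame(
    subject_id = rep(subject_id, nrow(candidates)),
    start_s = round(candidates$start_s, 3),
    end_s = round(candidates$end_s, 3),
    peak_envelope_uv = candidates$peak_envelope_uv,
    clip_start_s = round(pmax(0, candidates$start_s - clip_pad_s), 3),
    clip_end_s = round(candidates$end_s + clip_pad_s, 3),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
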