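#' ictalkit: seizure quantification for rodent hippocampal LFP
#'
#' Tools for quantifying electrographic seizures and flagging large
#' behavioral seizures (LBSs) in chronic single-channel local field
#' potential recordings, together with a ground-truthed synthetic LFP
#' generator and the behavioral metrics used alongside such recordings
#' (discrimination index, memory-test exclusion rules, sucrose-consumption
#' summaries, extended Racine scoring).
#'
#' @section Pipeline:
#' \enumerate{
#'   \item [generate_background()], [embed_seizure()], [embed_lbs()],
#'     [generate_cohort()] build ground-truthed synthetic recordings.
#'   \item [estimate_baseline_amplitude()] and [detect_spikes()] find
#'     suprathreshold ictal spikes.
#'   \item [assemble_seizures()], [classify_hpd()], [duration_sweep()],
#'     [summarize_subject()] turn spikes into seizure events and burden
#'     summaries.
#'   \item [bandpass_envelope()], [smooth_envelope()], [flag_candidates()]
#'     implement the envelope pipeline that flags candidate LBSs for
#'     manual review.
#'   \item [discrimination_index()], [apply_memory_exclusions()],
#'     [sct_summary()], [lbs_burden()] cover the behavioral side.
#' }
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft median rnorm runif rpois quantile approx
#' @importFrom utils read.csv write.csv modifyList
NULL

# ---------------------------------------------------------------------------
# LfpRecording
# ---------------------------------------------------------------------------

#' Construct an LFP recording
#'
#' A uniformly sampled single-channel voltage trace with its sampling rate
#' and subject identity. Amplitudes are in microvolts throughout the
#' package; event times are seconds from recording start, on half-open
#' intervals `[start_s, end_s)`.
#'
#' @param samples Numeric vector of voltage samples (microvolts). All values
#'   must be finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param subject_id Subject identifier.
#' @param start_offset Seconds from session start to the first sample.
#' @return An object of class `lfp_recording` with fields `samples`,
#'   `sampling_rate`, `subject_id`, `start_offset`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 8 * seq(0, 1, by = 1e-3)), 1000)
#' lfp_duration(rec)
#' @export
lfp_recording <- function(samples, sampling_rate, subject_id = "unknown",
                          start_offset = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number", call. = FALSE)
  }
  if (length(samples) == 0L) {
    stop("samples must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id)[1L],
      samples = samples,
      sampling_rate = as.numeric(sampling_rate),
      start_offset = as.numeric(start_offset)[1L]
    ),
    class = "lfp_recording"
  )
}

#' Duration of a recording in seconds
#'
#' @param recording An [lfp_recording()].
#' @return `length(samples) / sampling_rate`, in seconds.
#' @export
lfp_duration <- function(recording) {
  stopifnot(inherits(recording, "lfp_recording"))
  length(recording$samples) / recording$sampling_rate
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> subject %s: %.1f s at %g Hz (%d samples), RMS %.1f uV\n",
    x$subject_id, lfp_duration(x), x$sampling_rate, length(x$samples),
    sqrt(mean((x$samples - mean(x$samples))^2))
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# DetectionParams
# ---------------------------------------------------------------------------

#' Electrographic seizure detection parameters
#'
#' Tunable thresholds of the spike detector and seizure assembler, with the
#' published global defaults: a seizure requires at least
#' `min_spikes_per_bin` (4) spikes exceeding `spike_threshold_factor` (2)
#' times the baseline amplitude within each `bin_width_s` (2 s) bin;
#' interictal periods are at least `min_interictal_gap_s` (1 s); the
#' minimum seizure duration is `min_seizure_duration_s` (3 s). Spike width
#' and refractory bounds were customized per subject in the original
#' workflow and are exposed here with declared (non-published) defaults.
#'
#' @param spike_threshold_factor Spike threshold as a multiple of the
#'   baseline amplitude (default 2).
#' @param min_spikes_per_bin Minimum spikes per bin for ictal density
#'   (default 4).
#' @param bin_width_s Bin width in seconds (default 2).
#' @param min_interictal_gap_s Minimum interictal (spike-free) period in
#'   seconds separating distinct events (default 1).
#' @param min_seizure_duration_s Minimum seizure duration in seconds
#'   (default 3).
#' @param spike_width_min_ms,spike_width_max_ms Acceptable spike width
#'   bounds in milliseconds, measured as time above half the detection
#'   threshold (defaults 5 and 200).
#' @param min_interspike_interval_ms Refractory interval between retained
#'   spikes, in milliseconds (default 40).
#' @param baseline_amplitude_uv Optional fixed baseline amplitude in
#'   microvolts; when `NA` (default) it is estimated from the recording by
#'   [estimate_baseline_amplitude()].
#' @return An object of class `detection_params`.
#' @seealso [validate_params()], [detect_spikes()], [assemble_seizures()]
#' @examples
#' p <- detection_params()
#' p$min_spikes_per_bin
#' @export
detection_params <- function(spike_threshold_factor = 2,
                             min_spikes_per_bin = 4,
                             bin_width_s = 2,
                             min_interictal_gap_s = 1,
                             min_seizure_duration_s = 3,
                             spike_width_min_ms = 5,
                             spike_width_max_ms = 200,
                             min_interspike_interval_ms = 40,
                             baseline_amplitude_uv = NA_real_) {
  params <- structure(
    list(
      spike_threshold_factor = as.numeric(spike_threshold_factor),
      min_spikes_per_bin = as.numeric(min_spikes_per_bin),
      bin_width_s = as.numeric(bin_width_s),
      min_interictal_gap_s = as.numeric(min_interictal_gap_s),
      min_seizure_duration_s = as.numeric(min_seizure_duration_s),
      spike_width_min_ms = as.numeric(spike_width_min_ms),
      spike_width_max_ms = as.numeric(spike_width_max_ms),
      min_interspike_interval_ms = as.numeric(min_interspike_interval_ms),
      baseline_amplitude_uv = as.numeric(baseline_amplitude_uv)
    ),
    class = "detection_params"
  )
  validate_params(params)
}

#' Validate detection parameters
#'
#' Checks every invariant of [detection_params()] and reports the first
#' violated one by field name.
#'
#' @param params A `detection_params` object (or a bare list with the same
#'   fields).
#' @return `params`, unchanged, if all invariants hold.
#' @examples
#' validate_params(detection_params())
#' @export
validate_params <- function(params) {
  fields <- c(
    "spike_threshold_factor", "min_spikes_per_bin", "bin_width_s",
    "min_interictal_gap_s", "min_seizure_duration_s", "spike_width_min_ms",
    "spike_width_max_ms", "min_interspike_interval_ms"
  )
  for (f in fields) {
    v <- params[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("%s must be a single finite number", f), call. = FALSE)
    }
    if (v <= 0) {
      stop(sprintf("%s must be positive", f), call. = FALSE)
    }
  }
  if (params$min_spikes_per_bin != round(params$min_spikes_per_bin) ||
      params$min_spikes_per_bin < 1) {
    stop("min_spikes_per_bin must be a positive integer", call. = FALSE)
  }
  if (params$spike_width_min_ms >= params$spike_width_max_ms) {
    stop("spike_width_min_ms must be less than spike_width_max_ms",
         call. = FALSE)
  }
  b <- params$baseline_amplitude_uv
  if (!is.null(b) && length(b) == 1L && !is.na(b) && b <= 0) {
    stop("baseline_amplitude_uv must be positive when supplied",
         call. = FALSE)
  }
  params
}

#' @export
print.detection_params <- function(x, ...) {
  cat("<detection_params>\n")
  for (f in names(x)) cat(sprintf("  %s = %s\n", f, format(x[[f]])))
  invisible(x)
}

# ---------------------------------------------------------------------------
# HpdCriteria
# ---------------------------------------------------------------------------

#' Hippocampal paroxysmal discharge (HPD) criteria
#'
#' An event is an HPD when its mean spike rate is at least
#' `min_spike_rate_hz` (5 Hz) and its duration at least `min_duration_s`
#' (5 s); both comparisons are inclusive.
#'
#' @param min_spike_rate_hz Minimum mean intra-event spike rate, Hz.
#' @param min_duration_s Minimum event duration, seconds.
#' @return An object of class `hpd_criteria`.
#' @export
hpd_criteria <- function(min_spike_rate_hz = 5, min_duration_s = 5) {
  if (!is.finite(min_spike_rate_hz) || min_spike_rate_hz <= 0) {
    stop("min_spike_rate_hz must be positive", call. = FALSE)
  }
  if (!is.finite(min_duration_s) || min_duration_s <= 0) {
    stop("min_duration_s must be positive", call. = FALSE)
  }
  structure(
    list(
      min_spike_rate_hz = as.numeric(min_spike_rate_hz),
      min_duration_s = as.numeric(min_duration_s)
    ),
    class = "hpd_criteria"
  )
}

# ---------------------------------------------------------------------------
# Extended Racine scale
# ---------------------------------------------------------------------------

#' Extended Racine scale stage descriptions
#'
#' Ordinal behavioral seizure severity stages 1-8, from a sudden change in
#' behavioral state up to violent jumping followed by sustained tonus.
#' Stages above 3 define large behavioral seizures (LBSs).
#'
#' @format Character vector of length 8; element `i` describes stage `i`.
#' @export
racine_stage_descriptions <- c(
  "sudden change in behavioral state",
  "head nodding",
  "forelimb clonus",
  "rearing, bucking, or clonus while on the stomach",
  "falling or clonus while on a side",
  "repeated sequences of rearing and falling, or brief jumps",
  "violent jumping",
  "violent jumping followed by a period of tonus lasting more than 5 s"
)

#' Construct an extended Racine score
#'
#' @param stage Integer stage in 1..8.
#' @return An object of class `racine_score` with fields `stage`,
#'   `description`, and `is_lbs` (`TRUE` iff `stage > 3`).
#' @examples
#' racine_score(5)$is_lbs
#' @export
racine_score <- function(stage) {
  if (length(stage) != 1L || !is.finite(stage) || stage != round(stage) ||
      stage < 1 || stage > 8) {
    stop("stage must be an integer in 1..8", call. = FALSE)
  }
  stage <- as.integer(stage)
  structure(
    list(
      stage = stage,
      description = racine_stage_descriptions[stage],
      is_lbs = stage > 3L
    ),
    class = "racine_score"
  )
}

#' Is a Racine stage a large behavioral seizure?
#'
#' LBSs are defined as stages strictly greater than 3 on the extended
#' Racine scale.
#'
#' @param stage Integer vector of stages in 1..8.
#' @return Logical vector.
#' @export
is_lbs <- function(stage) {
  if (any(!is.finite(stage) | stage < 1 | stage > 8)) {
    stop("stages must lie in 1..8", call. = FALSE)
  }
  stage > 3
}

# ---------------------------------------------------------------------------
# Parameter file round-trip (flat key/value text, one file per subject)
# ---------------------------------------------------------------------------

#' Write detection parameters to a flat key/value file
#'
#' One `key = value` line per field, keys named exactly as the
#' [detection_params()] fields. Values are written with full precision so
#' that [read_detection_params()] reproduces the parameter set exactly.
#'
#' @param params A `detection_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detection_params <- function(params, path) {
  params <- validate_params(params)
  lines <- vapply(names(params), function(f) {
    v <- params[[f]]
    sprintf("%s = %s", f,
            if (is.na(v)) "NA" else formatC(v, digits = 17, format = "g"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read detection parameters from a flat key/value file
#'
#' @param path File written by [write_detection_params()] (or by hand, one
#'   `key = value` pair per line; `#` starts a comment).
#' @return A validated `detection_params` object. Missing keys take their
#'   defaults; unknown keys are an error.
#' @export
read_detection_params <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) {
    stop(sprintf("malformed parameter line: '%s'", lines[bad][1L]),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  defaults <- detection_params()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown parameter key: '%s'", unknown[1L]), call. = FALSE)
  }
  args <- as.list(defaults)
  for (i in seq_along(keys)) {
    args[[keys[i]]] <- if (identical(vals[i], "NA")) NA_real_
                       else as.numeric(vals[i])
  }
  do.call(detection_params, args)
}
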