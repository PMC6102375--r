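# Ground-truthed synthetic chronic LFP: background rhythms, embedded ictal
# spike trains, large-amplitude behavioral-seizure episodes, and sparse
# artifact transients. Every embedded event is logged in a ground-truth
# table so detector stages can be scored without any recorded data.

KIND_SEIZURE <- "electrographic_seizure"
KIND_LBS <- "lbs"
KIND_ARTIFACT <- "artifact"

#' Create an empty ground-truth table
#'
#' Ground truth is a data frame of embedded-event intervals with columns
#' `subject_id`, `kind` (one of `"electrographic_seizure"`, `"lbs"`,
#' `"artifact"`), `start_s`, `end_s`, `spike_rate_hz`, `amplitude_factor`.
#' Intervals of the same kind never overlap.
#'
#' @return A zero-row ground-truth data frame.
#' @export
empty_ground_truth <- function() {
  data.frame(
    subject_id = character(0),
    kind = character(0),
    start_s = numeric(0),
    end_s = numeric(0),
    spike_rate_hz = numeric(0),
    amplitude_factor = numeric(0),
    stringsAsFactors = FALSE
  )
}

# Append one interval, enforcing the same-kind non-overlap invariant.
add_truth_interval <- function(truth, subject_id, kind, start_s, end_s,
                               spike_rate_hz = NA_real_,
                               amplitude_factor = NA_real_) {
  same <- truth[truth$kind == kind, , drop = FALSE]
  if (nrow(same) > 0L && any(start_s < same$end_s & end_s > same$start_s)) {
    stop(sprintf("interval [%g, %g) overlaps an existing '%s' interval",
                 start_s, end_s, kind), call. = FALSE)
  }
  out <- rbind(truth, data.frame(
    subject_id = subject_id, kind = kind, start_s = start_s, end_s = end_s,
    spike_rate_hz = spike_rate_hz, amplitude_factor = amplitude_factor,
    stringsAsFactors = FALSE
  ))
  out[order(out$start_s), , drop = FALSE]
}

#' Generate background LFP
#'
#' Emulates seizure-free (saline-control-like) hippocampal background:
#' 1/f-family noise (amplitude spectrum proportional to
#' `f^-spectral_exponent` above `corner_hz`, flat below it, DC removed)
#' plus low-amplitude theta (8 Hz, 25% of total RMS) and gamma (40 Hz,
#' 10% of total RMS) oscillations with random phases. The default
#' exponent 1.5 (power falling as `f^-3`) gives the slow-wave-dominated
#' spectrum typical of resting hippocampal LFP, in which suprathreshold
#' excursions are slow and wide rather than spike-like. The overall
#' root-mean-square amplitude is `rms_uv`. Deterministic for a fixed
#' `seed`.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param seed Integer RNG seed.
#' @param rms_uv Target overall RMS amplitude in microvolts (default 50).
#' @param subject_id Subject identifier attached to the recording.
#' @param theta_frac,gamma_frac RMS fractions of the theta and gamma
#'   components (defaults 0.25 and 0.10).
#' @param spectral_exponent Amplitude-spectrum exponent of the noise
#'   component (default 1.5).
#' @param corner_hz Frequency below which the noise spectrum is flat
#'   (default 0.5 Hz).
#' @return An [lfp_recording()].
#' @examples
#' rec <- generate_background(10, 1000, seed = 1)
#' sqrt(mean(rec$samples^2))
#' @export
generate_background <- function(duration_s, sampling_rate = 1000, seed = 1,
                                rms_uv = 50, subject_id = "synthetic",
                                theta_frac = 0.25, gamma_frac = 0.10,
                                spectral_exponent = 1.5, corner_hz = 0.5) {
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- round(duration_s * sampling_rate)
  t <- seq_len(n) / sampling_rate

  # 1/f-family noise via spectral shaping; flat below corner_hz, zero DC.
  w <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * sampling_rate / n
  weight <- 1 / pmax(f, corner_hz)^spectral_exponent
  weight[1L] <- 0
  pink <- Re(stats::fft(w * weight, inverse = TRUE)) / n
  pink <- pink / sqrt(mean(pink^2))

  theta <- sqrt(2) * sin(2 * pi * 8 * t + stats::runif(1, 0, 2 * pi))
  gamma <- sqrt(2) * sin(2 * pi * 40 * t + stats::runif(1, 0, 2 * pi))
  pink_frac <- sqrt(max(0, 1 - theta_frac^2 - gamma_frac^2))

  samples <- rms_uv * (pink_frac * pink + theta_frac * theta +
                         gamma_frac * gamma)
  lfp_recording(samples, sampling_rate, subject_id = subject_id)
}

# Normalized biphasic spike waveform: sharp positive lobe of the given
# Gaussian sigma followed by a slower negative lobe. Peak value is 1.
biphasic_spike_waveform <- function(sigma_s, sampling_rate) {
  half_left <- 4 * sigma_s
  half_right <- 2.2 * sigma_s + 4 * 1.8 * sigma_s
  tt <- seq(-half_left, half_right, by = 1 / sampling_rate)
  shape <- exp(-tt^2 / (2 * sigma_s^2)) -
    0.45 * exp(-(tt - 2.2 * sigma_s)^2 / (2 * (1.8 * sigma_s)^2))
  list(shape = shape / max(shape),
       peak_offset = which.max(shape) - 1L)
}

# Add a waveform to the samples so that its peak lands at peak_index.
add_waveform_at <- function(samples, waveform, peak_index) {
  i0 <- peak_index - waveform$peak_offset
  idx <- seq(i0, i0 + length(waveform$shape) - 1L)
  keep <- idx >= 1L & idx <= length(samples)
  samples[idx[keep]] <- samples[idx[keep]] + waveform$shape[keep]
  samples
}

#' Embed an ictal spike train into a recording
#'
#' Inserts a train of biphasic sharp transients with jittered inter-spike
#' intervals (uniform +/-20% around `1/spike_rate_hz`) and peak amplitude
#' `amplitude_factor` times the recording's baseline amplitude. During the
#' event the ongoing background is attenuated to
#' `background_suppression` of its amplitude (with half-cosine ramps at
#' the edges), reflecting that ictal discharges dominate the local field
#' rather than superimposing on unchanged background activity -- and
#' guaranteeing that every inserted spike actually exceeds the detection
#' threshold, so the ground truth stays consistent with the trace. The
#' event is appended to the ground-truth table with kind
#' `"electrographic_seizure"`. Uses the current RNG state; seed the RNG
#' (or use [generate_cohort()]) for reproducibility.
#'
#' @param recording An [lfp_recording()].
#' @param truth Ground-truth table (see [empty_ground_truth()]).
#' @param start_s,duration_s Event interval, seconds; must lie inside the
#'   recording.
#' @param spike_rate_hz Nominal spike rate in Hz (> 0).
#' @param amplitude_factor Spike peak as a multiple of the baseline
#'   amplitude. `0` leaves the trace unchanged (truth is still recorded).
#' @param width_range_ms Range of full-width-at-half-maximum values (ms)
#'   from which each spike's width is drawn (default `c(10, 50)`).
#' @param baseline_uv Baseline amplitude to scale against; estimated from
#'   the recording when `NULL`.
#' @param background_suppression Fraction of the background amplitude kept
#'   inside the event (default 0.3).
#' @return A list with elements `recording` and `truth`.
#' @export
embed_seizure <- function(recording, truth, start_s, duration_s,
                          spike_rate_hz, amplitude_factor,
                          width_range_ms = c(10, 50), baseline_uv = NULL,
                          background_suppression = 0.3) {
  stopifnot(inherits(recording, "lfp_recording"))
  dur <- lfp_duration(recording)
  if (start_s < 0 || start_s + duration_s > dur) {
    stop("event interval lies outside the recording", call. = FALSE)
  }
  if (!is.finite(spike_rate_hz) || spike_rate_hz <= 0) {
    stop("spike_rate_hz must be positive", call. = FALSE)
  }
  truth <- add_truth_interval(truth, recording$subject_id, KIND_SEIZURE,
                              start_s, start_s + duration_s,
                              spike_rate_hz, amplitude_factor)
  if (is.null(baseline_uv)) {
    baseline_uv <- estimate_baseline_amplitude(recording)
  }
  fs <- recording$sampling_rate
  isi <- 1 / spike_rate_hz
  tt <- start_s + isi * stats::runif(1, 0.3, 0.7)
  times <- numeric(0)
  while (tt < start_s + duration_s) {
    times <- c(times, tt)
    tt <- tt + isi * stats::runif(1, 0.8, 1.2)
  }
  samples <- recording$samples
  if (amplitude_factor > 0 && background_suppression < 1) {
    idx <- (round(start_s * fs) + 1L):round((start_s + duration_s) * fs)
    scale <- rep(background_suppression, length(idx))
    ramp_n <- min(round(0.25 * fs), floor(length(idx) / 4))
    if (ramp_n > 0L) {
      edge <- background_suppression + (1 - background_suppression) *
        0.5 * (1 + cos(pi * seq_len(ramp_n) / ramp_n))
      scale[seq_len(ramp_n)] <- edge
      scale[length(idx) - seq_len(ramp_n) + 1L] <- edge
    }
    samples[idx] <- samples[idx] * scale
  }
  amp <- amplitude_factor * baseline_uv
  for (tm in times) {
    fwhm_ms <- stats::runif(1, width_range_ms[1L], width_range_ms[2L])
    sigma_s <- fwhm_ms / 1000 / 2.3548
    wf <- biphasic_spike_waveform(sigma_s, fs)
    wf$shape <- wf$shape * amp
    samples <- add_waveform_at(samples, wf, round(tm * fs) + 1L)
  }
  recording$samples <- samples
  list(recording = recording, truth = truth)
}

#' Embed a large-behavioral-seizure-like episode
#'
#' Inserts sustained large-amplitude band-limited (20-200 Hz) activity --
#' the band the LBS flagger passes -- with RMS amplitude
#' `amplitude_factor` times the baseline amplitude, tapered at both edges
#' with a half-cosine ramp. The event is appended to the ground truth with
#' kind `"lbs"`.
#'
#' @inheritParams embed_seizure
#' @param band_hz Frequency band of the inserted activity (default
#'   `c(20, 200)`).
#' @param ramp_s Edge taper length in seconds (shrunk for short events).
#' @return A list with elements `recording` and `truth`.
#' @export
embed_lbs <- function(recording, truth, start_s, duration_s,
                      amplitude_factor, band_hz = c(20, 200), ramp_s = 0.5,
                      baseline_uv = NULL) {
  stopifnot(inherits(recording, "lfp_recording"))
  dur <- lfp_duration(recording)
  if (start_s < 0 || start_s + duration_s > dur) {
    stop("event interval lies outside the recording", call. = FALSE)
  }
  truth <- add_truth_interval(truth, recording$subject_id, KIND_LBS,
                              start_s, start_s + duration_s,
                              NA_real_, amplitude_factor)
  if (is.null(baseline_uv)) {
    baseline_uv <- estimate_baseline_amplitude(recording)
  }
  fs <- recording$sampling_rate
  n_ev <- round(duration_s * fs)
  if (n_ev < 4L) {
    return(list(recording = recording, truth = truth))
  }
  w <- stats::fft(stats::rnorm(n_ev))
  k <- seq_len(n_ev) - 1L
  f <- pmin(k, n_ev - k) * fs / n_ev
  w[f < band_hz[1L] | f > band_hz[2L]] <- 0
  burst <- Re(stats::fft(w, inverse = TRUE)) / n_ev
  burst <- burst / sqrt(mean(burst^2)) * amplitude_factor * baseline_uv
  ramp_n <- min(round(ramp_s * fs), floor(n_ev / 4))
  if (ramp_n > 0L) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    burst[seq_len(ramp_n)] <- burst[seq_len(ramp_n)] * ramp
    burst[n_ev - ramp_n + seq_len(ramp_n)] <-
      burst[n_ev - ramp_n + seq_len(ramp_n)] * rev(ramp)
  }
  i0 <- round(start_s * fs) + 1L
  idx <- seq(i0, length.out = n_ev)
  idx <- idx[idx <= length(recording$samples)]
  recording$samples[idx] <- recording$samples[idx] + burst[seq_along(idx)]
  list(recording = recording, truth = truth)
}

#' Embed sparse artifact transients
#'
#' Isolated single biphasic transients (amplitude uniform between
#' `min_factor` and `max_factor` times baseline) at Poisson-distributed
#' times, emulating movement/chewing artifacts. Single spikes must not
#' assemble into seizures under the spikes-per-bin rule; these stress the
#' detector's false-positive behavior. Each transient is logged with kind
#' `"artifact"`.
#'
#' @inheritParams embed_seizure
#' @param rate_per_min Expected artifact rate per minute.
#' @param min_factor,max_factor Amplitude bounds as baseline multiples
#'   (defaults 2 and 3).
#' @return A list with elements `recording` and `truth`.
#' @export
embed_artifacts <- function(recording, truth, rate_per_min = 1,
                            min_factor = 2, max_factor = 3,
                            baseline_uv = NULL) {
  stopifnot(inherits(recording, "lfp_recording"))
  dur <- lfp_duration(recording)
  if (is.null(baseline_uv)) {
    baseline_uv <- estimate_baseline_amplitude(recording)
  }
  n_art <- stats::rpois(1, rate_per_min * dur / 60)
  if (n_art == 0L) {
    return(list(recording = recording, truth = truth))
  }
  times <- sort(stats::runif(n_art, 0.5, dur - 0.5))
  # keep artifacts isolated: drop any within 1 s of the previous one
  keep <- c(TRUE, diff(times) >= 1)
  times <- times[keep]
  fs <- recording$sampling_rate
  samples <- recording$samples
  for (tm in times) {
    amp <- stats::runif(1, min_factor, max_factor) * baseline_uv
    fwhm_ms <- stats::runif(1, 10, 50)
    wf <- biphasic_spike_waveform(fwhm_ms / 1000 / 2.3548, fs)
    wf$shape <- wf$shape * amp
    samples <- add_waveform_at(samples, wf, round(tm * fs) + 1L)
    truth <- add_truth_interval(truth, recording$subject_id, KIND_ARTIFACT,
                                tm - 0.05, tm + 0.15, NA_real_, NA_real_)
  }
  recording$samples <- samples
  list(recording = recording, truth = truth)
}

# ---------------------------------------------------------------------------
# Cohort scenarios
# ---------------------------------------------------------------------------

# Fill one subject scenario entry with defaults and validate it.
normalize_subject_scenario <- function(s, index) {
  defaults <- list(
    id = sprintf("subj%02d", index),
    duration_s = 3600,
    sampling_rate = 1000,
    rms_uv = 50,
    artifact_rate_per_min = 1,
    seizures = list(),
    lbs = list()
  )
  s <- utils::modifyList(defaults, as.list(s))
  ev_defaults <- list(
    seizures = list(n = NULL, rate_per_h = 0, spike_rate_hz = 8,
                    amplitude_factor = 4, duration_range = c(4, 12)),
    lbs = list(n = NULL, rate_per_h = 0, amplitude_factor = 8,
               duration_range = c(30, 60))
  )
  for (kind in c("seizures", "lbs")) {
    e <- utils::modifyList(ev_defaults[[kind]], as.list(s[[kind]]))
    e$duration_range <- as.numeric(unlist(e$duration_range))
    if (length(e$duration_range) != 2L || any(e$duration_range <= 0)) {
      stop(sprintf("malformed scenario: %s duration_range for subject %s",
                   kind, s$id), call. = FALSE)
    }
    if (is.null(e$n)) {
      e$n <- round(e$rate_per_h * s$duration_s / 3600)
    }
    s[[kind]] <- e
  }
  if (!is.finite(s$duration_s) || s$duration_s <= 0) {
    stop("malformed scenario: duration_s must be positive", call. = FALSE)
  }
  s
}

#' Generate a ground-truthed synthetic cohort
#'
#' Builds one recording per subject listed in `scenario`, embedding the
#' programmed numbers of electrographic seizures and LBS episodes at
#' randomized, non-overlapping positions (events are placed one per equal
#' time slot with at least ~10 s separation), plus Poisson artifact
#' transients. A "saline" scenario (zero event rates) embeds no seizures
#' and no LBSs. Fully reproducible for a fixed `seed`.
#'
#' @param scenario A list with element `subjects`: a list of per-subject
#'   entries with fields `id`, `duration_s`, `sampling_rate`, `rms_uv`,
#'   `artifact_rate_per_min`, `seizures` (`n` or `rate_per_h`,
#'   `spike_rate_hz`, `amplitude_factor`, `duration_range`) and `lbs`
#'   (`n` or `rate_per_h`, `amplitude_factor`, `duration_range`). Missing
#'   fields take defaults; `n = round(rate_per_h * hours)` when only a rate
#'   is given. See [read_scenario()] for the on-disk YAML form.
#' @param seed Integer seed controlling every random draw.
#' @return A list with one element per subject, each a list
#'   `(recording, truth)`.
#' @examples
#' sc <- list(subjects = list(list(id = "m1", duration_s = 120,
#'   seizures = list(n = 2, duration_range = c(6, 10)))))
#' cohort <- generate_cohort(sc, seed = 1)
#' cohort[[1]]$truth
#' @export
generate_cohort <- function(scenario, seed = 1) {
  if (is.null(scenario$subjects) || length(scenario$subjects) == 0L) {
    stop("malformed scenario: no subjects", call. = FALSE)
  }
  out <- vector("list", length(scenario$subjects))
  names(out) <- vapply(seq_along(scenario$subjects), function(i) {
    normalize_subject_scenario(scenario$subjects[[i]], i)$id
  }, character(1))
  for (i in seq_along(scenario$subjects)) {
    s <- normalize_subject_scenario(scenario$subjects[[i]], i)
    subject_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    rec <- generate_background(s$duration_s, s$sampling_rate,
                               seed = subject_seed, rms_uv = s$rms_uv,
                               subject_id = s$id)
    truth <- empty_ground_truth()
    base_uv <- estimate_baseline_amplitude(rec)

    n_total <- s$seizures$n + s$lbs$n
    if (n_total > 0L) {
      kinds <- sample(c(rep(KIND_SEIZURE, s$seizures$n),
                        rep(KIND_LBS, s$lbs$n)))
      slot_len <- s$duration_s / n_total
      max_dur <- max(c(if (s$seizures$n > 0) s$seizures$duration_range[2L],
                       if (s$lbs$n > 0) s$lbs$duration_range[2L]))
      margin <- 5
      if (slot_len < max_dur + 2 * margin) {
        stop(sprintf(
          "malformed scenario: subject %s too dense (%d events of up to %g s in %g s)",
          s$id, n_total, max_dur, s$duration_s), call. = FALSE)
      }
      for (j in seq_len(n_total)) {
        slot_start <- (j - 1L) * slot_len
        if (kinds[j] == KIND_SEIZURE) {
          dr <- s$seizures$duration_range
          ev_dur <- stats::runif(1, dr[1L], dr[2L])
          ev_start <- slot_start +
            stats::runif(1, margin, slot_len - ev_dur - margin)
          res <- embed_seizure(rec, truth, ev_start, ev_dur,
                               s$seizures$spike_rate_hz,
                               s$seizures$amplitude_factor,
                               baseline_uv = base_uv)
        } else {
          dr <- s$lbs$duration_range
          ev_dur <- stats::runif(1, dr[1L], dr[2L])
          ev_start <- slot_start +
            stats::runif(1, margin, slot_len - ev_dur - margin)
          res <- embed_lbs(rec, truth, ev_start, ev_dur,
                           s$lbs$amplitude_factor, baseline_uv = base_uv)
        }
        rec <- res$recording
        truth <- res$truth
      }
    }
    if (s$artifact_rate_per_min > 0) {
      res <- embed_artifacts(rec, truth, s$artifact_rate_per_min,
                             baseline_uv = base_uv)
      rec <- res$recording
      truth <- res$truth
    }
    out[[i]] <- list(recording = rec, truth = truth)
  }
  out
}

#' Read or write a cohort scenario (YAML)
#'
#' Scenario files are YAML documents mirroring the list accepted by
#' [generate_cohort()].
#'
#' @param path Scenario file path.
#' @return `read_scenario()` returns the scenario list; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("scenario file not found: %s", path), call. = FALSE)
  }
  sc <- yaml::read_yaml(path)
  if (is.null(sc$subjects)) {
    stop("malformed scenario: missing 'subjects'", call. = FALSE)
  }
  sc
}

#' @rdname read_scenario
#' @param scenario Scenario list.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(scenario, path)
  invisible(path)
}

#' Write or read a ground-truth table (CSV)
#'
#' Columns: `subject_id`, `kind`, `start_s`, `end_s`, `spike_rate_hz`,
#' `amplitude_factor`.
#'
#' @param truth Ground-truth data frame.
#' @param path CSV path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("ground-truth file not found: %s", path), call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}
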