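# Assemble detected spikes into electrographic seizures: a seizure needs at
# least min_spikes_per_bin spikes within each bin_width_s window, a
# spike-free interval of at least min_interictal_gap_s terminates an event
# (interictal period), and events shorter than min_seizure_duration_s are
# discarded. Events are trimmed to the first/last spike they contain.

# Merge sorted intervals; also merge across gaps smaller than `gap`.
merge_intervals <- function(starts, ends, gap = 0) {
  if (length(starts) == 0L) {
    return(list(start = numeric(0), end = numeric(0)))
  }
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  ms <- starts[1L]
  me <- ends[1L]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] - me < gap) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- starts[i]
      me <- ends[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

empty_event_table <- function() {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    duration_s = numeric(0), spike_count = integer(0),
                    mean_spike_rate_hz = numeric(0), is_hpd = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("seizure_table", "data.frame")
  out
}

#' Assemble spikes into electrographic seizures
#'
#' Spikes are first split into clusters wherever consecutive spikes are
#' separated by at least `min_interictal_gap_s` of spike-free time (an
#' interictal period, which no seizure may span). Within a cluster, the
#' ictal density rule applies: with the default sliding mode, a time point
#' is ictal when the window of length `bin_width_s` centered on it
#' contains at least `min_spikes_per_bin` of the cluster's spikes; the
#' resulting ictal regions (merged when separated by less than the
#' interictal gap) are trimmed to the first and last spike they contain
#' and become candidate events. `mode = "tumbling"` instead counts spikes
#' in fixed consecutive bins `[0, w), [w, 2w), ...` and joins adjacent
#' ictal bins; it is provided for comparison with fixed-bin
#' implementations. Candidates then pass [filter_by_min_duration()] with
#' `params$min_seizure_duration_s`, and each event's HPD flag is set per
#' `criteria`.
#'
#' @param spikes A `spike_table` (from [detect_spikes()]) or any data
#'   frame with a `time_s` column, sorted or not.
#' @param recording_duration_s Duration of the analyzed recording in
#'   seconds; all spikes must lie in `[0, recording_duration_s)`.
#' @param params [detection_params()].
#' @param criteria [hpd_criteria()] used to set `is_hpd`.
#' @param mode `"sliding"` (default) or `"tumbling"`.
#' @param apply_min_duration Set `FALSE` to keep sub-threshold-duration
#'   events (used by [duration_sweep()]).
#' @return A `seizure_table` data frame with columns `start_s`, `end_s`,
#'   `duration_s`, `spike_count`, `mean_spike_rate_hz`, `is_hpd`; events
#'   are sorted, non-overlapping, and separated by at least
#'   `min_interictal_gap_s`.
#' @examples
#' spikes <- data.frame(time_s = seq(0, 5.9, by = 0.1))
#' assemble_seizures(spikes, 60, detection_params())
#' @export
assemble_seizures <- function(spikes, recording_duration_s,
                              params = detection_params(),
                              criteria = hpd_criteria(),
                              mode = c("sliding", "tumbling"),
                              apply_min_duration = TRUE) {
  params <- validate_params(params)
  mode <- match.arg(mode)
  t <- sort(as.numeric(spikes$time_s))
  if (length(t) > 0L &&
      (min(t) < 0 || max(t) >= recording_duration_s)) {
    stop("spikes outside [0, recording_duration_s)", call. = FALSE)
  }
  k <- as.integer(params$min_spikes_per_bin)
  w <- params$bin_width_s
  gap <- params$min_interictal_gap_s
  if (length(t) < k) {
    return(empty_event_table())
  }

  # Interictal split: a spike-free interval >= gap ends any event.
  cluster <- cumsum(c(0, diff(t) >= gap))
  ev_start <- numeric(0)
  ev_end <- numeric(0)
  for (cl in unique(cluster)) {
    tc <- t[cluster == cl]
    n <- length(tc)
    if (n < k) next
    if (mode == "sliding") {
      # k consecutive spikes spanning <= w are covered by some window
      # centered in [t[i+k-1] - w/2, t[i] + w/2].
      i <- seq_len(n - k + 1L)
      span_ok <- tc[i + k - 1L] - tc[i] <= w
      if (!any(span_ok)) next
      i <- i[span_ok]
      reg <- merge_intervals(tc[i + k - 1L] - w / 2, tc[i] + w / 2,
                             gap = gap)
    } else {
      bins <- floor(tc / w)
      counts <- table(bins)
      hot <- as.numeric(names(counts))[counts >= k]
      if (length(hot) == 0L) next
      reg <- merge_intervals(hot * w, (hot + 1) * w, gap = gap)
    }
    # Trim each region to the first/last cluster spike it contains.
    for (j in seq_along(reg$start)) {
      inside <- tc[tc >= reg$start[j] & tc <= reg$end[j]]
      if (length(inside) >= k) {
        ev_start <- c(ev_start, inside[1L])
        ev_end <- c(ev_end, inside[length(inside)])
      }
    }
  }
  if (length(ev_start) == 0L) {
    return(empty_event_table())
  }
  o <- order(ev_start)
  ev_start <- ev_start[o]
  ev_end <- ev_end[o]
  counts <- vapply(seq_along(ev_start), function(j) {
    sum(t >= ev_start[j] & t <= ev_end[j])
  }, numeric(1))
  dur <- ev_end - ev_start
  keep <- dur > 0
  out <- data.frame(
    start_s = ev_start[keep], end_s = ev_end[keep],
    duration_s = dur[keep], spike_count = as.integer(counts[keep]),
    mean_spike_rate_hz = counts[keep] / dur[keep],
    stringsAsFactors = FALSE
  )
  out$is_hpd <- classify_hpd(out, criteria)
  class(out) <- c("seizure_table", "data.frame")
  if (apply_min_duration) {
    out <- filter_by_min_duration(out, params$min_seizure_duration_s)
  }
  out
}

#' Filter events by minimum duration
#'
#' Keeps exactly the events whose duration is greater than or equal to
#' `min_duration_s` (the comparison is inclusive, matching the "minimum
#' duration" phrasing; the published default minimum is 3 s).
#'
#' @param events A `seizure_table`.
#' @param min_duration_s Non-negative threshold in seconds; 0 is the
#'   identity.
#' @return The filtered `seizure_table`.
#' @export
filter_by_min_duration <- function(events, min_duration_s) {
  if (!is.finite(min_duration_s) || min_duration_s < 0) {
    stop("min_duration_s must be non-negative", call. = FALSE)
  }
  out <- events[events$duration_s >= min_duration_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify hippocampal paroxysmal discharges
#'
#' An event is an HPD when its mean spike rate is at least
#' `criteria$min_spike_rate_hz` and its duration at least
#' `criteria$min_duration_s`; both comparisons are inclusive, so an event
#' at exactly 5 Hz for exactly 5 s qualifies.
#'
#' @param events A `seizure_table` (or data frame with
#'   `mean_spike_rate_hz` and `duration_s` columns).
#' @param criteria [hpd_criteria()].
#' @return Logical vector, one element per event.
#' @examples
#' classify_hpd(data.frame(mean_spike_rate_hz = 5, duration_s = 5))
#' @export
classify_hpd <- function(events, criteria = hpd_criteria()) {
  events$mean_spike_rate_hz >= criteria$min_spike_rate_hz &
    events$duration_s >= criteria$min_duration_s
}

#' Seizure rate in events per hour
#'
#' @param events A `seizure_table`.
#' @param analyzed_hours Hours of data analyzed (> 0).
#' @return `nrow(events) / analyzed_hours`.
#' @export
seizure_rate <- function(events, analyzed_hours) {
  if (!is.finite(analyzed_hours) || analyzed_hours <= 0) {
    stop("analyzed_hours must be positive", call. = FALSE)
  }
  nrow(events) / analyzed_hours
}

#' Seizure rate as a function of minimum duration
#'
#' Assembles events once (without the duration filter), then filters at
#' each candidate minimum duration. Because filtering only removes
#' events, the resulting rates are non-increasing in the threshold --
#' the structure behind duration-distribution plots of seizure frequency.
#'
#' @inheritParams assemble_seizures
#' @param min_durations Ascending numeric vector of minimum durations (s).
#' @param analyzed_hours Hours analyzed; defaults to
#'   `recording_duration_s / 3600`.
#' @return A data frame with columns `min_duration_s` and
#'   `events_per_hour`.
#' @export
duration_sweep <- function(spikes, recording_duration_s,
                           params = detection_params(),
                           min_durations = c(3, 5, 10, 20, 30),
                           analyzed_hours = recording_duration_s / 3600,
                           criteria = hpd_criteria(),
                           mode = "sliding") {
  if (is.unsorted(min_durations)) {
    stop("min_durations must be sorted ascending", call. = FALSE)
  }
  events <- assemble_seizures(spikes, recording_duration_s, params,
                              criteria = criteria, mode = mode,
                              apply_min_duration = FALSE)
  rates <- vapply(min_durations, function(d) {
    seizure_rate(filter_by_min_duration(events, d), analyzed_hours)
  }, numeric(1))
  data.frame(min_duration_s = min_durations, events_per_hour = rates)
}

#' Per-subject seizure burden summary
#'
#' @param events A `seizure_table` for one subject.
#' @param analyzed_hours Hours of data analyzed (> 0).
#' @return A one-row data frame: `n_events`, `events_per_hour`,
#'   `mean_duration_s`, `median_duration_s`, `n_hpd`, `hpd_per_hour`.
#'   Duration statistics are `NA` when there are no events.
#' @export
summarize_subject <- function(events, analyzed_hours) {
  if (!is.finite(analyzed_hours) || analyzed_hours <= 0) {
    stop("analyzed_hours must be positive", call. = FALSE)
  }
  n <- nrow(events)
  data.frame(
    n_events = n,
    events_per_hour = n / analyzed_hours,
    mean_duration_s = if (n > 0) mean(events$duration_s) else NA_real_,
    median_duration_s = if (n > 0) stats::median(events$duration_s)
                        else NA_real_,
    n_hpd = sum(events$is_hpd),
    hpd_per_hour = sum(events$is_hpd) / analyzed_hours
  )
}

#' Write or read a seizure event table (CSV)
#'
#' Columns: `subject_id`, `start_s`, `end_s`, `duration_s`, `spike_count`,
#' `mean_spike_rate_hz`, `is_hpd`; times written with 3-decimal precision.
#'
#' @param events A `seizure_table`.
#' @param path CSV path.
#' @param subject_id Subject identifier column value.
#' @return `write_event_table()` returns `path` invisibly;
#'   `read_event_table()` returns the data frame.
#' @export
write_event_table <- function(events, path, subject_id = "unknown") {
  out <- data.frame(
    subject_id = rep(subject_id, nrow(events)),
    start_s = round(events$start_s, 3),
    end_s = round(events$end_s, 3),
    duration_s = round(events$duration_s, 3),
    spike_count = events$spike_count,
    mean_spike_rate_hz = events$mean_spike_rate_hz,
    is_hpd = events$is_hpd,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("event table not found: %s", path), call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a spike table (CSV)
#'
#' Columns: `subject_id`, `time_s`, `amplitude_uv`, `width_ms`,
#' `polarity`; times written with 3-decimal precision.
#'
#' @param spikes A `spike_table` from [detect_spikes()].
#' @param path CSV path.
#' @param subject_id Subject identifier column value.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(spikes, path, subject_id = "unknown") {
  out <- data.frame(
    subject_id = rep(subject_id, nrow(spikes)),
    time_s = round(spikes$time_s, 3),
    amplitude_uv = spikes$amplitude_uv,
    width_ms = spikes$width_ms,
    polarity = spikes$polarity,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
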