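# Independent brute-force oracles. These apply the detection and assembly
# rules literally, by exhaustive scanning, with no shared code with the
# package implementations they check.

# Literal spike detector: scan every sample for local maxima of |x - mean|
# above threshold, expand each run sample-by-sample for the width rule,
# then apply the refractory rule greedily by descending amplitude.
# Returns sorted kept peak indices (1-based).
oracle_detect_spike_indices <- function(x, fs, params, baseline) {
  y <- abs(x - mean(x))
  thr <- params$spike_threshold_factor * baseline
  half <- thr / 2
  n <- length(y)
  cand <- integer(0)
  for (i in 2:(n - 1L)) {
    if (y[i] >= y[i - 1L] && y[i] > y[i + 1L] && y[i] > thr) {
      cand <- c(cand, i)
    }
  }
  keep <- integer(0)
  widths <- numeric(0)
  for (i in cand) {
    l <- i
    while (l > 1L && y[l - 1L] >= half) l <- l - 1L
    r <- i
    while (r < n && y[r + 1L] >= half) r <- r + 1L
    w_ms <- (r - l + 1L) / fs * 1000
    if (w_ms >= params$spike_width_min_ms &&
        w_ms <= params$spike_width_max_ms) {
      keep <- c(keep, i)
      widths <- c(widths, w_ms)
    }
  }
  min_gap <- params$min_interspike_interval_ms / 1000 * fs
  ord <- order(-y[keep], keep)
  kept <- integer(0)
  for (j in ord) {
    p <- keep[j]
    if (length(kept) == 0L || all(abs(kept - p) >= min_gap)) {
      kept <- c(kept, p)
    }
  }
  sort(kept)
}

# Literal seizure assembler: O(n^2) enumeration of all spike pairs (i, j)
# holding >= k spikes within the window span, interval stacking, merging,
# trimming, and duration filtering -- at spike-time resolution.
oracle_assemble <- function(times, duration_s, params) {
  t <- sort(times)
  k <- params$min_spikes_per_bin
  w <- params$bin_width_s
  gap <- params$min_interictal_gap_s
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    spike_count = integer(0))
  if (length(t) < k) return(out)

  cluster <- integer(length(t))
  cluster[1L] <- 1L
  for (i in seq_along(t)[-1L]) {
    cluster[i] <- cluster[i - 1L] + as.integer(t[i] - t[i - 1L] >= gap)
  }
  for (cl in unique(cluster)) {
    tc <- t[cluster == cl]
    n <- length(tc)
    if (n < k) next
    starts <- numeric(0)
    ends <- numeric(0)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j >= i && j - i + 1L >= k && tc[j] - tc[i] <= w) {
          starts <- c(starts, tc[j] - w / 2)
          ends <- c(ends, tc[i] + w / 2)
        }
      }
    }
    if (length(starts) == 0L) next
    o <- order(starts)
    starts <- starts[o]
    ends <- ends[o]
    ms <- starts[1L]
    me <- ends[1L]
    regions <- NULL
    for (i in seq_along(starts)[-1L]) {
      if (starts[i] - me < gap) {
        me <- max(me, ends[i])
      } else {
        regions <- rbind(regions, c(ms, me))
        ms <- starts[i]
        me <- ends[i]
      }
    }
    regions <- rbind(regions, c(ms, me))
    for (r in seq_len(nrow(regions))) {
      inside <- tc[tc >= regions[r, 1L] & tc <= regions[r, 2L]]
      if (length(inside) >= k) {
        out <- rbind(out, data.frame(start_s = inside[1L],
                                     end_s = inside[length(inside)],
                                     spike_count = length(inside)))
      }
    }
  }
  out <- out[out$end_s - out$start_s >= params$min_seizure_duration_s, ,
             drop = FALSE]
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random spike trains mixing dense bursts with sprinkled singles.
random_spike_train <- function(n_max = 200, duration_s = 60) {
  n_bursts <- sample(0:4, 1)
  times <- numeric(0)
  for (b in seq_len(n_bursts)) {
    start <- runif(1, 0, duration_s - 10)
    rate <- runif(1, 2, 12)
    len <- runif(1, 1, 8)
    times <- c(times, start + cumsum(rexp(ceiling(rate * len), rate)))
  }
  times <- c(times, runif(sample(0:30, 1), 0, duration_s))
  times <- sort(times[times < duration_s - 1e-6 & times >= 0])
  if (length(times) > n_max) times <- sort(sample(times, n_max))
  times
}

# Small synthetic trace with Gaussian bumps on a slow sine, for the
# spike-detector oracle.
bump_trace <- function(fs, duration_s, bump_times, bump_amps, bump_sigmas_ms,
                       slow_amp = 10, noise_sd = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- slow_amp * sin(2 * pi * 0.5 * t)
  if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
  for (i in seq_along(bump_times)) {
    s <- bump_sigmas_ms[i] / 1000
    x <- x + bump_amps[i] * exp(-(t - bump_times[i])^2 / (2 * s^2))
  }
  x
}
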