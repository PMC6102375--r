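test_that("baseline estimator matches closed forms and is seizure-robust", {
  fs <- 1000
  # pure sine, peak 100 uV: robust estimate = 1.18294 * 100 / sqrt(2)
  sine <- lfp_recording(100 * sin(2 * pi * 8 * seq(0, 20 - 1 / fs, by = 1 / fs)), fs)
  expect_equal(estimate_baseline_amplitude(sine), 83.65, tolerance = 0.01)
  # plain rectified mean of a sine: 2 * 100 / pi
  expect_equal(estimate_baseline_amplitude(sine, method = "mean"),
               200 / pi, tolerance = 0.01)

  # a seizure covering 5% of the recording shifts the estimate by < 10%
  rec <- generate_background(120, fs, seed = 21)
  clean <- estimate_baseline_amplitude(rec)
  set.seed(21)
  res <- embed_seizure(rec, empty_ground_truth(), 50, 6, 10, 4,
                       baseline_uv = clean)
  dirty <- estimate_baseline_amplitude(res$recording)
  expect_lt(abs(dirty - clean) / clean, 0.10)

  expect_error(estimate_baseline_amplitude(
    lfp_recording(rep(0, 20000), fs)), "degenerate")
  expect_error(estimate_baseline_amplitude(
    lfp_recording(rnorm(100), fs)), "at least")
})

test_that("detector finds embedded transients and ignores silence", {
  fs <- 1000
  p <- detection_params(baseline_amplitude_uv = 25)
  expect_equal(nrow(detect_spikes(lfp_recording(rep(0, 20000), fs), p)), 0)

  rec <- generate_background(30, fs, seed = 22)
  base <- estimate_baseline_amplitude(rec)
  set.seed(22)
  res <- embed_seizure(rec, empty_ground_truth(), 5, 6, 10, 4,
                       baseline_uv = base)
  # ground truth at the spike level: peaks of the inserted waveform train
  diffsig <- res$recording$samples - rec$samples
  n <- length(diffsig)
  truth_idx <- 1 + which(diffsig[2:(n - 1)] >= diffsig[1:(n - 2)] &
                           diffsig[2:(n - 1)] > diffsig[3:n] &
                           diffsig[2:(n - 1)] > 2 * base)
  truth_t <- (truth_idx - 1) / fs
  expect_gte(length(truth_t), 58)
  expect_lte(length(truth_t), 62)

  sp <- detect_spikes(res$recording, detection_params())
  # a spike may be picked at its negative after-lobe, up to ~50 ms from
  # the inserted peak; 60 ms is still under the 80 ms minimum ISI here
  matched <- vapply(truth_t, function(tt) any(abs(sp$time_s - tt) < 0.06),
                    logical(1))
  expect_gte(sum(matched), length(truth_t) - 2)
  expect_true(all(diff(sp$time_s) >= 0))
  expect_true(all(sp$width_ms >= 5 & sp$width_ms <= 200))
})

test_that("refractory rule keeps the larger of two close peaks", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- 100 * exp(-(t - 1)^2 / (2 * 0.002^2)) +
    80 * exp(-(t - 1.01)^2 / (2 * 0.002^2))
  p <- detection_params(baseline_amplitude_uv = 25)
  sp <- detect_spikes(lfp_recording(x, fs), p)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$time_s, 1, tolerance = 1e-3)
  expect_equal(sp$amplitude_uv, max(abs(x - mean(x))), tolerance = 1e-6)
  expect_equal(sp$polarity, "positive")
})

test_that("spike count is monotone in threshold factor and scale-equivariant", {
  rec <- generate_background(60, 1000, seed = 23)
  base <- estimate_baseline_amplitude(rec)
  set.seed(23)
  res <- embed_seizure(rec, empty_ground_truth(), 10, 10, 8, 4,
                       baseline_uv = base)
  counts <- vapply(c(1.5, 2, 2.5, 3, 4, 6), function(f) {
    nrow(detect_spikes(res$recording,
                       detection_params(spike_threshold_factor = f,
                                        baseline_amplitude_uv = base)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[2], 0)

  # multiplying trace and baseline by a constant leaves detections unchanged
  scaled <- res$recording
  scaled$samples <- scaled$samples * 3.7
  a <- detect_spikes(res$recording,
                     detection_params(baseline_amplitude_uv = base))
  b <- detect_spikes(scaled,
                     detection_params(baseline_amplitude_uv = base * 3.7))
  expect_equal(a$time_s, b$time_s)
  expect_equal(a$width_ms, b$width_ms)
  expect_equal(b$amplitude_uv, a$amplitude_uv * 3.7, tolerance = 1e-12)
})

test_that("detector matches the literal brute-force oracle on small traces", {
  fs <- 1000
  p <- detection_params(baseline_amplitude_uv = 10)
  set.seed(31)
  for (rep in 1:8) {
    n_b <- sample(3:12, 1)
    x <- bump_trace(fs, 10,
                    bump_times = sort(runif(n_b, 0.5, 9.5)),
                    bump_amps = runif(n_b, 15, 60) * sample(c(-1, 1), n_b,
                                                            replace = TRUE),
                    bump_sigmas_ms = runif(n_b, 1, 40),
                    slow_amp = 8, noise_sd = 2)
    rec <- lfp_recording(x, fs)
    got <- detect_spikes(rec, p)
    want_idx <- oracle_detect_spike_indices(x, fs, p, 10)
    expect_equal(round(got$time_s * fs) + 1L, want_idx)
  }
})
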