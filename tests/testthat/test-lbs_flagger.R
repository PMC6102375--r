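test_that("bandpass envelope passes in-band sines flat and kills out-of-band", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  p <- lbs_flag_params()

  env50 <- bandpass_envelope(lfp_recording(100 * sin(2 * pi * 50 * t), fs), p)
  mid <- env50[500:1500]
  expect_equal(mean(mid), 100, tolerance = 0.01)
  expect_lt((max(mid) - min(mid)) / mean(mid), 0.05)

  env5 <- bandpass_envelope(lfp_recording(100 * sin(2 * pi * 5 * t), fs), p)
  expect_lt(max(env5[500:1500]), 1)

  expect_true(all(env50 >= 0))
  expect_error(
    bandpass_envelope(lfp_recording(rnorm(1000), 300), p),
    "Nyquist"
  )
})

test_that("envelope energy agrees with a time-domain bandpass oracle", {
  fs <- 1000
  rec <- generate_background(60, fs, seed = 51)
  set.seed(51)
  res <- embed_lbs(rec, empty_ground_truth(), 20, 20, 8)
  p <- lbs_flag_params()
  env <- bandpass_envelope(res$recording, p)

  # oracle: Butterworth time-domain bandpass + rectification; for a
  # narrowband signal mean|x_bp| = (2/pi) * mean envelope
  bw <- signal::butter(3, c(20, 200) / (fs / 2), type = "pass")
  xbp <- signal::filtfilt(bw, res$recording$samples)
  seg <- seq(22 * fs, 38 * fs)
  expect_equal(mean(env[seg]), mean(abs(xbp[seg])) * pi / 2,
               tolerance = 0.10)
})

test_that("spectral-zeroing modes behave as documented", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- 100 * sin(2 * pi * 50 * t)
  p <- lbs_flag_params()

  # symmetric mode returns the rectified real band-limited signal
  sym <- bandpass_envelope(lfp_recording(x, fs), p, mode = "symmetric")
  expect_equal(sym[500:1500], abs(x)[500:1500], tolerance = 1e-6)

  # literal printed index arithmetic collapses to a no-op at fs = 1000
  rec <- lfp_recording(x + 30, fs)
  expect_equal(bandpass_envelope(rec, p, mode = "printed"),
               abs(rec$samples), tolerance = 1e-9)
})

test_that("the zero-phase smoother has unit DC gain and no phase lag", {
  p <- lbs_flag_params()
  expect_equal(smooth_envelope(rep(10, 4000), p, 1000), rep(10, 4000),
               tolerance = 1e-9)

  # time-reversal symmetry
  set.seed(52)
  x <- abs(cumsum(rnorm(20000)) / 20) + 5
  p1 <- lbs_flag_params(smoother_cutoff_hz = 1)
  a <- smooth_envelope(x, p1, 1000)
  b <- rev(smooth_envelope(rev(x), p1, 1000))
  expect_equal(a, b, tolerance = 1e-6)

  # step: midpoint crossing has no lag; transition is monotone up to
  # the small ripple a squared Butterworth leaves
  fs <- 200
  step_at <- 30
  x <- c(rep(0, step_at * fs), rep(10, step_at * fs))
  s <- smooth_envelope(x, p1, fs)
  crossing <- which(s >= 5)[1] / fs
  expect_lt(abs(crossing - step_at), 0.1)
  trans <- s[((step_at - 2) * fs):((step_at + 2) * fs)]
  expect_lt(max(-diff(trans), 0), 0.02 * 10)

  expect_error(smooth_envelope(rep(1, 100), lbs_flag_params(
    smoother_cutoff_hz = 600), 1000), "Nyquist")
})

test_that("candidate flagging merges nearby bursts and respects thresholds", {
  fs <- 100
  env <- rep(1, 60 * fs)
  p <- lbs_flag_params(threshold_uv = 5, min_flag_gap_s = 10)
  expect_equal(nrow(flag_candidates(env, p, fs)), 0)

  # two suprathreshold bursts 5 s apart -> one merged candidate
  env[(10 * fs):(12 * fs)] <- 20
  env[(17 * fs):(19 * fs)] <- 20
  one <- flag_candidates(env, p, fs)
  expect_equal(nrow(one), 1)
  expect_equal(one$peak_envelope_uv, 20)

  # 12 s apart -> two candidates, sorted and non-overlapping
  env2 <- rep(1, 60 * fs)
  env2[(10 * fs):(12 * fs)] <- 20
  env2[(24 * fs):(26 * fs)] <- 20
  two <- flag_candidates(env2, p, fs)
  expect_equal(nrow(two), 2)
  expect_true(all(two$end_s[-2] <= two$start_s[-1]))

  expect_error(flag_candidates(env, lbs_flag_params(), fs), "threshold_uv")
})

test_that("suggested thresholds scale with the trace and flag all embedded LBS", {
  expect_equal(suggest_threshold(envelope = rep(10, 1000), k = 5), 50)

  rec <- generate_background(600, 1000, seed = 53)
  thr1 <- suggest_threshold(rec, allow_short = TRUE)
  scaled <- rec
  scaled$samples <- scaled$samples * 2.5
  expect_equal(suggest_threshold(scaled, allow_short = TRUE), 2.5 * thr1,
               tolerance = 1e-9)
  expect_error(suggest_threshold(rec), "allow_short")
  expect_error(suggest_threshold(envelope = rep(0, 100)), "degenerate")

  # saline background: the suggested threshold yields zero flags
  res_sal <- flag_lbs(rec, lbs_flag_params())
  expect_equal(nrow(res_sal$candidates), 0)

  # embedded LBS: every truth interval overlaps exactly one candidate
  set.seed(53)
  base <- estimate_baseline_amplitude(rec)
  truth <- empty_ground_truth()
  work <- rec
  for (s in c(100, 280, 460)) {
    r <- embed_lbs(work, truth, s, 40, 8, baseline_uv = base)
    work <- r$recording
    truth <- r$truth
  }
  res <- flag_lbs(work, lbs_flag_params())
  for (i in seq_len(nrow(truth))) {
    overlaps <- res$candidates$start_s < truth$end_s[i] &
      res$candidates$end_s > truth$start_s[i]
    expect_equal(sum(overlaps), 1)
  }
})
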