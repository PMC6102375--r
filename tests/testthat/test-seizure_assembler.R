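p_default <- detection_params()

train <- function(start, dur, rate) {
  start + seq(0, dur, by = 1 / rate)
}

test_that("an isolated dense train becomes one event of the right extent", {
  t <- train(10, 5.9, 10) # 60 spikes over 5.9 s
  ev <- assemble_seizures(data.frame(time_s = t), 60, p_default)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 10)
  expect_equal(ev$end_s, 15.9)
  expect_equal(ev$spike_count, 60)
  expect_equal(ev$mean_spike_rate_hz, 60 / 5.9)
  expect_true(ev$is_hpd)
})

test_that("sparse spikes never assemble", {
  expect_equal(nrow(assemble_seizures(data.frame(time_s = c(1, 20, 40)),
                                      60, p_default)), 0)
  # 4-in-2s but spanning < 3 s: removed by the duration filter
  expect_equal(nrow(assemble_seizures(
    data.frame(time_s = c(10, 10.3, 10.6, 10.9)), 60, p_default)), 0)
  expect_error(assemble_seizures(data.frame(time_s = c(-1, 5, 6, 7)), 60,
                                 p_default), "outside")
})

test_that("the interictal gap rule merges sub-1 s gaps and splits longer ones", {
  merged <- assemble_seizures(
    data.frame(time_s = c(train(10, 4, 10), train(14.8, 4, 10))),
    60, p_default)
  expect_equal(nrow(merged), 1)

  split <- assemble_seizures(
    data.frame(time_s = c(train(10, 4, 10), train(15.5, 4, 10))),
    60, p_default)
  expect_equal(nrow(split), 2)
  # events are sorted, non-overlapping, with gaps >= the interictal minimum
  expect_true(all(diff(split$start_s) > 0))
  expect_true(all(split$start_s[-1] - split$end_s[-nrow(split)] >=
                    p_default$min_interictal_gap_s))
})

test_that("assembly is idempotent on an assembled event's own spikes", {
  set.seed(41)
  t <- sort(c(train(5, 8, 9) + runif(73, 0, 0.01)))
  ev <- assemble_seizures(data.frame(time_s = t), 60, p_default)
  expect_equal(nrow(ev), 1)
  inside <- t[t >= ev$start_s & t <= ev$end_s]
  ev2 <- assemble_seizures(data.frame(time_s = inside), 60, p_default)
  expect_equal(ev2$start_s, ev$start_s)
  expect_equal(ev2$end_s, ev$end_s)
  expect_equal(ev2$spike_count, ev$spike_count)
})

test_that("duration filtering is inclusive at the boundary", {
  ev <- data.frame(start_s = c(0, 10, 20), end_s = c(2.9, 13.0, 28),
                   duration_s = c(2.9, 3.0, 8), spike_count = c(10, 12, 30),
                   mean_spike_rate_hz = c(3.4, 4, 3.75),
                   is_hpd = c(FALSE, FALSE, FALSE))
  kept <- filter_by_min_duration(ev, 3)
  expect_equal(kept$duration_s, c(3.0, 8))
  expect_equal(nrow(filter_by_min_duration(ev, 0)), 3)
  expect_error(filter_by_min_duration(ev, -1), "non-negative")
})

test_that("HPD classification uses inclusive 5 Hz / 5 s boundaries", {
  ev <- data.frame(
    mean_spike_rate_hz = c(5.0, 4.9, 8.0, 5.0),
    duration_s = c(5.0, 10.0, 4.9, 20.0)
  )
  expect_identical(classify_hpd(ev, hpd_criteria()),
                   c(TRUE, FALSE, FALSE, TRUE))
})

test_that("seizure rates pool across concatenated recordings", {
  ev40 <- data.frame(start_s = seq_len(40), end_s = seq_len(40) + 0.5)
  expect_equal(seizure_rate(ev40, 2), 20)
  expect_equal(seizure_rate(ev40[0, ], 2), 0)
  expect_error(seizure_rate(ev40, 0), "positive")

  # rate over two recordings equals the pooled-count rate
  t1 <- train(10, 5, 10)
  t2 <- train(20, 7, 10)
  e1 <- assemble_seizures(data.frame(time_s = t1), 3600, p_default)
  e2 <- assemble_seizures(data.frame(time_s = t2), 3600, p_default)
  pooled <- (nrow(e1) + nrow(e2)) / 2
  expect_equal((seizure_rate(e1, 1) + seizure_rate(e2, 1)) / 2, pooled)
})

test_that("duration sweep rates are non-increasing and equal direct filtering", {
  set.seed(42)
  t <- sort(c(train(5, 6, 8), train(30, 12, 10), train(50, 4, 9),
              runif(20, 0, 60)))
  t <- t[t < 60]
  sw <- duration_sweep(data.frame(time_s = t), 60, p_default,
                       min_durations = c(3, 5, 7, 10),
                       analyzed_hours = 1 / 60)
  expect_true(all(diff(sw$events_per_hour) <= 0))

  all_ev <- assemble_seizures(data.frame(time_s = t), 60, p_default,
                              apply_min_duration = FALSE)
  for (i in seq_len(nrow(sw))) {
    expect_equal(sw$events_per_hour[i],
                 nrow(filter_by_min_duration(all_ev, sw$min_duration_s[i])) * 60)
  }

  one <- duration_sweep(data.frame(time_s = train(10, 5.9, 10)), 60,
                        p_default, min_durations = c(3, 7),
                        analyzed_hours = 1)
  expect_gt(one$events_per_hour[1], 0)
  expect_equal(one$events_per_hour[2], 0)
})

test_that("tumbling-bin mode also recovers a dense train", {
  t <- train(10, 5.9, 10)
  ev <- assemble_seizures(data.frame(time_s = t), 60, p_default,
                          mode = "tumbling")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$spike_count, 60)
})

test_that("subject summaries agree with direct table statistics", {
  t <- sort(c(train(5, 6, 8), train(30, 12, 10)))
  ev <- assemble_seizures(data.frame(time_s = t), 3600, p_default)
  s <- summarize_subject(ev, 1)
  expect_equal(s$n_events, nrow(ev))
  expect_equal(s$median_duration_s, median(sort(ev$duration_s)))
  expect_equal(s$mean_duration_s, mean(ev$duration_s))
  expect_equal(s$n_hpd, sum(ev$is_hpd))

  empty <- summarize_subject(ev[0, ], 2)
  expect_equal(empty$n_events, 0)
  expect_true(is.na(empty$median_duration_s))

  expect_equal(summarize_subject(
    data.frame(duration_s = c(4, 6, 8), is_hpd = rep(FALSE, 3)), 1
  )$median_duration_s, 6)
})

test_that("assembly matches the brute-force oracle on random spike trains", {
  set.seed(43)
  for (rep in 1:200) {
    t <- random_spike_train()
    got <- assemble_seizures(data.frame(time_s = t), 60, p_default)
    want <- oracle_assemble(t, 60, p_default)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$end_s, want$end_s)
    expect_equal(got$spike_count, want$spike_count)
  }
})
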