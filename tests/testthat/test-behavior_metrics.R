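test_that("discrimination index is the percent-scale contrast of exploration", {
  expect_equal(discrimination_index(6, 4), 20)
  expect_equal(discrimination_index(5, 5), 0)
  # antisymmetry and bounds on random pairs
  set.seed(61)
  nv <- runif(50, 0.1, 30)
  fm <- runif(50, 0.1, 30)
  di <- discrimination_index(nv, fm)
  expect_equal(di, -discrimination_index(fm, nv))
  expect_true(all(di >= -100 & di <= 100))
  expect_error(discrimination_index(0, 0), "zero total")
  expect_error(discrimination_index(-1, 2), "non-negative")
})

exploration_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(subject_id = r[[1]], session = r[[2]],
               novel_time_s = as.numeric(r[[3]]),
               familiar_time_s = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("memory exclusions use the quoted strict boundaries", {
  records <- exploration_df(
    # testing total 2.9 s -> excluded (< 3 s)
    list("a", "training", 5, 5), list("a", "testing", 1.5, 1.4),
    # testing total exactly 3 s -> kept
    list("b", "training", 5, 5), list("b", "testing", 1.5, 1.5),
    # training DI exactly 20 -> kept (rule is strictly > 20)
    list("c", "training", 6, 4), list("c", "testing", 7, 3),
    # training DI -25 -> excluded despite ample testing exploration
    list("d", "training", 3, 5), list("d", "testing", 6, 4)
  )
  res <- apply_memory_exclusions(records)
  expect_setequal(res$kept$subject_id, c("b", "c"))
  expect_equal(res$excluded$subject_id, c("a", "d"))
  expect_match(res$excluded$reason[1], "3 s")
  expect_match(res$excluded$reason[2], "training bias")

  # kept and excluded partition the input
  expect_setequal(c(res$kept$subject_id, res$excluded$subject_id),
                  unique(records$subject_id))
  expect_length(intersect(res$kept$subject_id, res$excluded$subject_id), 0)

  expect_error(apply_memory_exclusions(
    exploration_df(list("x", "training", 5, 5))), "testing")
})

test_that("sucrose summaries average by day type", {
  records <- rbind(
    data.frame(subject_id = "m1", day_index = 1,
               bottle_contents = c("water", "water"),
               consumed_g = c(1.8, 2.0)),
    data.frame(subject_id = "m1", day_index = 2,
               bottle_contents = c("water", "water"),
               consumed_g = c(2.0, 2.0)),
    data.frame(subject_id = "m1", day_index = 3,
               bottle_contents = c("water", "sucrose"),
               consumed_g = c(1.0, 11.0)),
    data.frame(subject_id = "m1", day_index = 4,
               bottle_contents = c("sucrose", "water"),
               consumed_g = c(12.0, 0.8))
  )
  s <- sct_summary(records)
  expect_equal(s$water_day_mean_g, mean(c(3.8, 4.0)))
  expect_equal(s$sucrose_day_mean_g, 11.5)
  expect_equal(s$n_water_days, 2)
  expect_equal(s$n_sucrose_days, 2)

  # oracle: direct group-by aggregation on a random table
  set.seed(62)
  big <- do.call(rbind, lapply(sprintf("s%d", 1:5), function(sid) {
    data.frame(subject_id = sid, day_index = rep(1:4, each = 2),
               bottle_contents = c(rep("water", 4),
                                   "water", "sucrose", "sucrose", "water"),
               consumed_g = round(runif(8, 0.5, 12), 2))
  }))
  got <- sct_summary(big)
  for (sid in unique(big$subject_id)) {
    r <- big[big$subject_id == sid, ]
    water <- mean(tapply(r$consumed_g[r$day_index <= 2],
                         r$day_index[r$day_index <= 2], sum))
    expect_equal(got$water_day_mean_g[got$subject_id == sid], water)
  }

  one <- sct_summary(data.frame(
    subject_id = "z", day_index = c(1, 1, 2, 2),
    bottle_contents = c("water", "water", "water", "sucrose"),
    consumed_g = c(2, 2, 1, 9)))
  expect_equal(one$water_day_mean_g, 4)
  expect_equal(one$sucrose_day_mean_g, 9)

  expect_error(sct_summary(data.frame(
    subject_id = "w", day_index = 1,
    bottle_contents = "water", consumed_g = 3)), "sucrose day")
})

test_that("LBS burden counts only stages above 3", {
  s <- lbs_burden(data.frame(stage = c(3, 4, 5),
                             duration_s = c(30, 40, 50)), 10)
  expect_equal(s$n_lbs, 2)
  expect_equal(s$lbs_per_day, 0.2)
  expect_equal(s$mean_lbs_duration_s, 45)
  expect_equal(s$median_lbs_stage, 4.5)

  none <- lbs_burden(data.frame(stage = c(1, 2, 3),
                                duration_s = c(10, 10, 10)), 5)
  expect_equal(none$n_lbs, 0)
  expect_true(is.na(none$median_lbs_stage))

  # median equals a sort-based oracle
  set.seed(63)
  stages <- sample(1:8, 40, replace = TRUE)
  b <- lbs_burden(data.frame(stage = stages, duration_s = runif(40, 20, 80)),
                  14)
  lbs_stages <- sort(stages[stages > 3])
  mid <- (lbs_stages[ceiling(length(lbs_stages) / 2)] +
            lbs_stages[floor(length(lbs_stages) / 2) + 1]) / 2
  expect_equal(b$median_lbs_stage, mid)
  expect_error(lbs_burden(data.frame(stage = 4, duration_s = 1), 0),
               "positive")
})
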