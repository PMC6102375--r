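# Behavioral quantities and exclusion rules: novel-object/novel-location
# discrimination index, pre-established memory-test exclusions, sucrose
# consumption summaries, and large-behavioral-seizure burden bookkeeping
# on the extended Racine scale.

#' Discrimination index (DI)
#'
#' The difference in time spent investigating the novel and familiar
#' objects divided by the total object exploration time, on a x100
#' (percent-like) scale: `100 * (novel - familiar) / (novel + familiar)`.
#' Bounded in `[-100, 100]`; positive values indicate preference for the
#' novel object/location.
#'
#' @param novel_time_s,familiar_time_s Exploration times in seconds
#'   (vectorized); each pair must have a positive sum.
#' @return Numeric DI value(s) on the percent scale.
#' @examples
#' discrimination_index(6, 4) # 20
#' @export
discrimination_index <- function(novel_time_s, familiar_time_s) {
  if (any(novel_time_s < 0 | familiar_time_s < 0)) {
    stop("exploration times must be non-negative", call. = FALSE)
  }
  total <- novel_time_s + familiar_time_s
  if (any(total <= 0)) {
    stop("zero total exploration: DI is undefined", call. = FALSE)
  }
  100 * (novel_time_s - familiar_time_s) / total
}

#' Apply pre-established memory-test exclusion rules
#'
#' A subject is excluded when its testing-session total object exploration
#' is strictly below 3 s, or when its training-session performance is
#' biased: `|training DI| > 20` (strictly greater; a subject at exactly 20
#' is kept). Each exclusion carries the rule that triggered it; a subject
#' failing both rules is reported with the exploration rule.
#'
#' @param records Data frame of exploration records with columns
#'   `subject_id`, `session` (`"training"` or `"testing"`),
#'   `novel_time_s`, `familiar_time_s`; exactly one training and one
#'   testing row per subject.
#' @param min_testing_exploration_s Exclusion threshold on testing-session
#'   total exploration (default 3 s, strict `<`).
#' @param max_training_abs_di Exclusion threshold on training |DI|
#'   (default 20, strict `>`).
#' @return A list with data frames `kept` (columns `subject_id`,
#'   `testing_di`, `testing_total_s`, `training_di`) and `excluded` (the
#'   same columns plus `reason`). Together they partition the input
#'   subjects.
#' @export
apply_memory_exclusions <- function(records,
                                    min_testing_exploration_s = 3,
                                    max_training_abs_di = 20) {
  needed <- c("subject_id", "session", "novel_time_s", "familiar_time_s")
  if (!all(needed %in% names(records))) {
    stop("records must have columns subject_id, session, novel_time_s, familiar_time_s",
         call. = FALSE)
  }
  subjects <- unique(records$subject_id)
  rows <- lapply(subjects, function(sid) {
    tr <- records[records$subject_id == sid & records$session == "training", ]
    te <- records[records$subject_id == sid & records$session == "testing", ]
    if (nrow(tr) != 1L || nrow(te) != 1L) {
      stop(sprintf("subject %s: need exactly one training and one testing record",
                   sid), call. = FALSE)
    }
    testing_total <- te$novel_time_s + te$familiar_time_s
    training_di <- discrimination_index(tr$novel_time_s, tr$familiar_time_s)
    testing_di <- if (testing_total > 0) {
      discrimination_index(te$novel_time_s, te$familiar_time_s)
    } else {
      NA_real_
    }
    reason <- NA_character_
    if (testing_total < min_testing_exploration_s) {
      reason <- sprintf("<%g s total testing exploration",
                        min_testing_exploration_s)
    } else if (abs(training_di) > max_training_abs_di) {
      reason <- sprintf("training bias: |DI| > %g", max_training_abs_di)
    }
    data.frame(subject_id = sid, testing_di = testing_di,
               testing_total_s = testing_total, training_di = training_di,
               reason = reason, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  excluded <- all[!is.na(all$reason), , drop = FALSE]
  kept <- all[is.na(all$reason), setdiff(names(all), "reason"),
              drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Sucrose consumption task (SCT) summary
#'
#' Summarizes daily bottle weights from the two-bottle sucrose
#' consumption task (two bottles per day; on sucrose days one bottle
#' holds a 4% sucrose solution). For each subject, returns the mean grams
#' consumed across water-only days (total of both bottles) and the mean
#' grams of sucrose solution consumed across sucrose days (the sucrose
#' bottle only).
#'
#' @param records Data frame with columns `subject_id`, `day_index`,
#'   `bottle_contents` (`"water"` or `"sucrose"`), `consumed_g`. A day is
#'   a sucrose day when any of its bottles contains sucrose. Every
#'   subject needs at least one water-only day and one sucrose day.
#' @return Data frame with columns `subject_id`, `water_day_mean_g`,
#'   `sucrose_day_mean_g`, `n_water_days`, `n_sucrose_days`.
#' @export
sct_summary <- function(records) {
  needed <- c("subject_id", "day_index", "bottle_contents", "consumed_g")
  if (!all(needed %in% names(records))) {
    stop("records must have columns subject_id, day_index, bottle_contents, consumed_g",
         call. = FALSE)
  }
  if (any(records$consumed_g < 0)) {
    stop("consumed_g must be non-negative", call. = FALSE)
  }
  subjects <- unique(records$subject_id)
  rows <- lapply(subjects, function(sid) {
    r <- records[records$subject_id == sid, ]
    day_has_sucrose <- tapply(r$bottle_contents == "sucrose", r$day_index,
                              any)
    sucrose_days <- names(day_has_sucrose)[day_has_sucrose]
    water_days <- names(day_has_sucrose)[!day_has_sucrose]
    if (length(water_days) == 0L || length(sucrose_days) == 0L) {
      stop(sprintf("subject %s: need at least one water-only and one sucrose day",
                   sid), call. = FALSE)
    }
    water_daily <- tapply(
      r$consumed_g[r$day_index %in% as.numeric(water_days)],
      r$day_index[r$day_index %in% as.numeric(water_days)], sum)
    sucrose_rows <- r[r$bottle_contents == "sucrose" &
                        r$day_index %in% as.numeric(sucrose_days), ]
    sucrose_daily <- tapply(sucrose_rows$consumed_g,
                            sucrose_rows$day_index, sum)
    data.frame(
      subject_id = sid,
      water_day_mean_g = mean(water_daily),
      sucrose_day_mean_g = mean(sucrose_daily),
      n_water_days = length(water_days),
      n_sucrose_days = length(sucrose_days),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Large-behavioral-seizure burden summary
#'
#' LBSs are seizure events scored above stage 3 on the extended Racine
#' scale. Returns their count, daily rate, mean duration, and the median
#' Racine stage among LBSs.
#'
#' @param scores Data frame with one row per scored seizure: columns
#'   `stage` (integer 1..8) and `duration_s`.
#' @param analyzed_days Days of observation (> 0).
#' @return A one-row data frame: `n_lbs`, `lbs_per_day`,
#'   `mean_lbs_duration_s`, `median_lbs_stage` (durations/stages `NA`
#'   when there are no LBSs).
#' @examples
#' lbs_burden(data.frame(stage = c(3, 4, 5), duration_s = c(30, 40, 50)), 10)
#' @export
lbs_burden <- function(scores, analyzed_days) {
  if (!is.finite(analyzed_days) || analyzed_days <= 0) {
    stop("analyzed_days must be positive", call. = FALSE)
  }
  lbs <- scores[is_lbs(scores$stage), , drop = FALSE]
  n <- nrow(lbs)
  data.frame(
    n_lbs = n,
    lbs_per_day = n / analyzed_days,
    mean_lbs_duration_s = if (n > 0) mean(lbs$duration_s) else NA_real_,
    median_lbs_stage = if (n > 0) stats::median(lbs$stage) else NA_real_
  )
}
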