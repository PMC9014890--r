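test_that("well-formed minute files read back in timestamp order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,steps,motion_intensity",
               "2020-02-17T09:00:00,12,2",
               "2020-02-17T09:01:00,0,1",
               "2020-02-17T09:05:00,40,3"), f)
  m <- read_minute_csv(f, id = "P001")
  expect_equal(nrow(m), 3)
  expect_equal(m$steps, c(12L, 0L, 40L))
  expect_true(all(diff(as.numeric(m$timestamp)) > 0))
  expect_equal(unique(m$participant_id), "P001")
})

test_that("malformed minute files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,steps", "2020-02-17T09:00:00,12"), f)
  expect_error(read_minute_csv(f), class = "wearweek_format_error")
  expect_error(read_minute_csv(f), "motion_intensity")

  writeLines(c("timestamp,steps,motion_intensity",
               "2020-02-17T09:00:00,12,2",
               "2020-02-17T09:00:00,3,1"), f)
  expect_error(read_minute_csv(f), class = "wearweek_validation_error")
  expect_error(read_minute_csv(f), "row 2")

  writeLines(c("timestamp,steps,motion_intensity",
               "2020-02-17T09:00:00,-1,2"), f)
  expect_error(read_minute_csv(f), class = "wearweek_validation_error")

  # steps without motion intensity violates the device-signal invariant
  writeLines(c("timestamp,steps,motion_intensity",
               "2020-02-17T09:00:00,10,0"), f)
  expect_error(read_minute_csv(f), class = "wearweek_validation_error")
})

test_that("minute write/read round trip is lossless on a synthetic cohort", {
  coh <- generate_cohort(synthetic_config(n_participants = 2, n_weeks = 2,
                                          closure_week = 2, seed = 11))
  d <- withr::local_tempdir()
  for (id in names(coh$minutes)) {
    p <- file.path(d, paste0(id, ".csv"))
    write_minute_csv(coh$minutes[[id]], p)
    back <- read_minute_csv(p)
    expect_equal(back, coh$minutes[[id]], ignore_attr = TRUE)
  }
})

test_that("epoch aggregation sums, maxes and counts per 15-minute grid cell", {
  m <- make_minutes("2020-02-17 09:00:00", steps = rep(10L, 15),
                    intensity = rep(2L, 15))
  ep <- aggregate_to_epochs(m)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$steps, 150L)
  expect_equal(ep$max_motion_intensity, 2L)
  expect_equal(ep$n_minutes_observed, 15L)
  expect_equal(format(ep$epoch_start, "%H:%M"), "09:00")

  s <- rep(0L, 15); s[8] <- 5L
  i <- rep(0L, 15); i[8] <- 1L
  ep2 <- aggregate_to_epochs(make_minutes("2020-02-17 09:00:00", s, i))
  expect_equal(ep2$steps, 5L)
  expect_equal(ep2$max_motion_intensity, 1L)

  empty <- make_minutes("2020-02-17 00:00:00", integer(0))
  expect_equal(nrow(aggregate_to_epochs(empty)), 0)
})

test_that("epoch aggregation matches per-cell recomputation over 48 h with gaps", {
  set.seed(42)
  t0 <- as.POSIXct("2020-02-17 00:00:00", tz = "UTC")
  keep <- sort(sample(0:(48 * 60 - 1), 1500))
  steps <- rpois(length(keep), 4)
  m <- data.frame(participant_id = "P001", timestamp = t0 + 60 * keep,
                  steps = steps,
                  motion_intensity = ifelse(steps > 0, 1L + steps %/% 5, 0L))
  ep <- aggregate_to_epochs(m)
  ref <- oracle_epochs(m)
  expect_equal(nrow(ep), nrow(ref))
  expect_equal(ep$steps, ref$steps)
  expect_equal(ep$max_motion_intensity, ref$max_motion_intensity)
  expect_equal(ep$n_minutes_observed, ref$n_minutes_observed)
  # conservation and max-domination invariants
  expect_equal(sum(ep$steps), sum(m$steps))
  expect_true(all(ep$max_motion_intensity %in% c(0, m$motion_intensity)))
})

test_that("day/week summary tables round trip through CSV", {
  days <- make_days(make_day(DAY1, 8000L, mvpa = 12L),
                    make_day(DAY1 + 5, 3000L, wear = 300L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_day_summaries(days, f)
  expect_equal(read_day_summaries(f), days, ignore_attr = TRUE)

  write_day_summaries(days[0, ], f)
  expect_equal(nrow(read_day_summaries(f)), 0)

  wk <- summarize_weeks(assign_study_weeks(days, study_design(DAY1)),
                        study_design(DAY1))
  g <- withr::local_tempfile(fileext = ".csv")
  write_week_summaries(wk, g)
  back <- read_week_summaries(g)
  expect_equal(back$steps_per_day, wk$steps_per_day, tolerance = 1e-12)
  expect_equal(back$is_valid_week, wk$is_valid_week)
  expect_equal(back$n_valid_weekdays, wk$n_valid_weekdays)
})

test_that("demographics tables validate their closed category sets", {
  dem <- generate_demographics(20, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_demographics_csv(dem, f)
  expect_equal(read_demographics_csv(f), dem, ignore_attr = TRUE)

  bad <- dem
  bad$gender[1] <- "unknown"
  expect_error(write_demographics_csv(bad, f),
               class = "wearweek_validation_error")
  dup <- dem
  dup$participant_id[2] <- dup$participant_id[1]
  expect_error(write_demographics_csv(dup, f),
               class = "wearweek_validation_error")
})
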