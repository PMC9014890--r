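test_that("nonwear rule flags only maximal zero-intensity runs of >= 3 epochs", {
  ep <- make_epochs(c(0, 0, 0, 2, 0, 0))
  expect_equal(detect_nonwear(ep), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))

  expect_equal(detect_nonwear(make_epochs(c(0, 0))), c(TRUE, TRUE))
  expect_equal(detect_nonwear(make_epochs(integer(0))), logical(0))

  # any nonzero-intensity epoch is always wear
  ep2 <- make_epochs(c(0, 0, 0, 0, 1, 0, 0, 0))
  expect_true(detect_nonwear(ep2)[5])

  expect_error(detect_nonwear(make_epochs(c(0, 1))[c(2, 1), ]),
               class = "wearweek_validation_error")
})

test_that("nonwear matches the brute-force scanner on random multi-day sequences", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(1:96, 1)
    intensity <- rbinom(n, 1, runif(1, 0.2, 0.8)) * sample(1:3, n, TRUE)
    ep <- make_epochs(intensity)
    expect_equal(detect_nonwear(ep), oracle_nonwear(intensity))
  }
})

test_that("zero-runs spanning midnight are split at midnight before the length test", {
  # two zero epochs before and one after midnight: neither day has a run >= 3
  ep <- make_epochs(c(2, 0, 0, 0, 2), start = "2020-02-17 23:15:00")
  expect_equal(detect_nonwear(ep), c(TRUE, TRUE, TRUE, TRUE, TRUE))
  # three zeros entirely before midnight do qualify
  ep2 <- make_epochs(c(0, 0, 0, 2), start = "2020-02-17 23:00:00")
  expect_equal(detect_nonwear(ep2), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("window wear minutes count worn epoch starts in [09:00, 21:00)", {
  ep <- make_epochs(rep(1L, 96), start = "2020-02-17 00:00:00")
  mask <- detect_nonwear(ep)
  expect_equal(wear_minutes_in_window(mask, ep, DAY1), 720L)

  # only 32 worn epochs inside the window: exactly the 8-hour boundary
  intensity <- rep(0L, 96)
  intensity[37:68] <- 1L  # epochs starting 09:00 .. 16:45
  ep2 <- make_epochs(intensity)
  expect_equal(wear_minutes_in_window(detect_nonwear(ep2), ep2, DAY1), 480L)

  # random masks vs direct enumeration over epoch starts
  set.seed(7)
  for (rep in 1:50) {
    m <- runif(96) < 0.5
    mod <- (0:95) * 15
    expect_equal(wear_minutes_in_window(m, ep, DAY1),
                 15L * sum(m & mod >= 540 & mod < 1260))
  }
})

test_that("MVPA bout rule counts run minutes and 10-minute walk bouts", {
  day <- "2020-02-17 10:00:00"
  expect_equal(detect_mvpa_minutes(make_minutes(day, rep(105L, 10))), 10L)
  idle <- rep(3L, 20)
  expect_equal(detect_mvpa_minutes(make_minutes(day, c(rep(105L, 9), idle))), 0L)
  expect_equal(detect_mvpa_minutes(make_minutes(day, c(140L, idle))), 1L)
  # absent minutes break walk-bout continuity
  split_walk <- rbind(make_minutes(day, rep(105L, 5)),
                      make_minutes("2020-02-17 10:30:00", rep(105L, 5)))
  expect_equal(detect_mvpa_minutes(split_walk), 0L)
  expect_error(
    detect_mvpa_minutes(rbind(make_minutes(day, rep(105L, 5)),
                              make_minutes("2020-02-18 10:00:00", rep(105L, 5)))),
    class = "wearweek_validation_error")
})

test_that("MVPA detector matches the window-enumeration oracle on random days", {
  set.seed(202)
  day <- "2020-02-17 08:00:00"
  for (rep in 1:200) {
    n <- sample(1:120, 1)
    cad <- sample(c(0L, 50L, 105L, 140L), n, replace = TRUE,
                  prob = c(0.4, 0.2, 0.25, 0.15))
    m <- make_minutes(day, cad)
    expect_equal(detect_mvpa_minutes(m), oracle_mvpa(cad))
  }
})

test_that("day summaries enforce both validity thresholds and skip empty days", {
  d1 <- DAY1
  # 8 h of wear in window + 600 steps -> valid
  base <- as.POSIXct("2020-02-17 09:00:00", tz = "UTC")
  m <- data.frame(participant_id = "P001",
                  timestamp = base + 60 * (0:479),
                  steps = c(rep(1L, 120), rep(1L, 480 - 120)),
                  motion_intensity = 1L)
  days <- process_participant_days(m)
  expect_equal(nrow(days), 1)
  expect_equal(days$wear_minutes_window, 480L)
  expect_false(days$is_valid)  # only 480 steps

  m$steps <- rep(2L, 480)  # 960 steps
  days2 <- process_participant_days(m)
  expect_true(days2$is_valid)

  # summarize_days: validity at the documented boundaries
  ep <- make_epochs(rep(1L, 96))
  mask <- rep(TRUE, 96)
  mins <- make_minutes("2020-02-17 10:00:00", rep(5L, 100))
  ep$steps <- rep(0L, 96)
  ep$steps[41] <- 499L
  s <- summarize_days(ep, mask, mins)
  expect_false(s$is_valid)   # 720 wear minutes but 499 steps
  ep$steps[41] <- 10000L
  expect_true(summarize_days(ep, mask, mins)$is_valid)
  s3 <- summarize_days(ep, c(rep(TRUE, 31 + 36), rep(FALSE, 29)), mins)
  expect_equal(s3$wear_minutes_window, 465L)  # 31 worn window epochs
  expect_false(s3$is_valid)
})

test_that("steps conservation: worn-epoch totals never exceed all-epoch totals", {
  set.seed(33)
  for (rep in 1:20) {
    intensity <- rbinom(96, 1, 0.6) * 2L
    steps <- ifelse(intensity > 0, rpois(96, 80), 0L)
    ep <- make_epochs(intensity, steps = steps)
    mask <- detect_nonwear(ep)
    mins <- make_minutes("2020-02-17 10:00:00", rep(0L, 1), rep(1L, 1))
    s <- summarize_days(ep, mask, mins)
    expect_lte(s$total_steps, sum(ep$steps))
    expect_equal(summarize_days(ep, rep(TRUE, 96), mins)$total_steps,
                 sum(ep$steps))
  }
})

test_that("day validity is monotone in wear minutes and steps", {
  cfg <- wear_config()
  grid <- expand.grid(wear = c(0L, 465L, 480L, 720L),
                      steps = c(0L, 499L, 500L, 10000L))
  valid <- with(grid, wear >= cfg$valid_day_min_wear_minutes &
                  steps >= cfg$valid_day_min_steps)
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      if (grid$wear[j] >= grid$wear[i] && grid$steps[j] >= grid$steps[i]) {
        expect_true(valid[j] >= valid[i])
      }
    }
  }
})
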