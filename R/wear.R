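# Wear processing: nonwear detection on the epoch grid, wear-time-in-window,
# bout-based MVPA minute detection, and per-day summaries.

#' Detect nonwear epochs
#'
#' An epoch is nonwear iff it belongs to a maximal run of at least
#' `nonwear_min_run_epochs` (default 3, i.e. >= 45 min) consecutive epochs
#' with zero maximum motion intensity. Runs are evaluated within each calendar
#' day independently: a zero-run spanning midnight is split at midnight before
#' the length test, because the day is the analysis unit. Any epoch with
#' nonzero intensity is always wear.
#'
#' @param epochs epoch data.frame (from [aggregate_to_epochs()], padded to
#'   full days if day-edge runs matter), ordered and gap-free on the
#'   15-minute grid.
#' @param config a [wear_config()].
#' @return logical vector aligned to `epochs` rows; `TRUE` = worn.
#' @examples
#' ep <- data.frame(participant_id = "P01",
#'                  epoch_start = as.POSIXct("2020-02-17", tz = "UTC") +
#'                    900 * (0:5),
#'                  steps = 0L,
#'                  max_motion_intensity = c(0L, 0L, 0L, 2L, 0L, 0L),
#'                  n_minutes_observed = 15L)
#' detect_nonwear(ep)  # FALSE FALSE FALSE TRUE TRUE TRUE
#' @export
detect_nonwear <- function(epochs, config = wear_config()) {
  n <- nrow(epochs)
  if (n == 0) return(logical(0))
  sec <- as.numeric(epochs$epoch_start)
  if (n > 1) {
    d <- diff(sec)
    ww_assert(all(d > 0), "epochs must be strictly ordered in time")
    ww_assert(all(d == 900),
              "epochs must be gap-free on the 15-minute grid")
  }
  ww_assert(all(sec %% 900 == 0), "epoch_start must lie on the 15-minute grid")
  zero <- epochs$max_motion_intensity == 0
  day <- sec %/% 86400
  # run-length encode zero-ness with breaks forced at day boundaries
  key <- paste0(as.integer(zero), ".", day)
  r <- rle(key)
  runlen <- rep.int(r$lengths, r$lengths)
  !(zero & runlen >= config$nonwear_min_run_epochs)
}

#' Wear minutes inside the daily window
#'
#' Counts 15 x (number of worn epochs of `date` whose start lies inside the
#' configured window, `[09:00, 21:00)` by default, half-open on epoch starts
#' so the default window holds exactly 48 epochs / 720 minutes).
#'
#' @param mask logical wear mask aligned to `epochs` (from [detect_nonwear()]).
#' @param epochs the epoch data.frame the mask was computed from.
#' @param date the calendar day (`Date`).
#' @param config a [wear_config()].
#' @return integer minutes in `[0, 720]` for the default window.
#' @export
wear_minutes_in_window <- function(mask, epochs, date, config = wear_config()) {
  ww_assert(length(mask) == nrow(epochs),
            "wear mask must align with the epoch sequence")
  mod <- ww_min_of_day(epochs$epoch_start)
  w0 <- hhmm_to_minutes(config$window_start)
  w1 <- hhmm_to_minutes(config$window_end)
  sel <- mask & ww_date(epochs$epoch_start) == as.Date(date) &
    mod >= w0 & mod < w1
  15L * sum(sel)
}

# core bout rule on a gap-free cadence vector (steps per minute):
# run minutes (cadence >= run threshold) count when in a consecutive run-block
# of >= run_bout minutes (default 1: always); walk minutes (walk <= cadence <
# run) count iff inside a maximal consecutive run of walk-or-run minutes of
# length >= walk_bout.
mvpa_minutes_from_cadence <- function(cadence, config = wear_config()) {
  if (length(cadence) == 0) return(0L)
  run <- cadence >= config$mvpa_run_cadence
  walk <- !run & cadence >= config$mvpa_walk_cadence
  active <- run | walk
  ra <- rle(active)
  active_len <- rep.int(ra$lengths, ra$lengths)
  rr <- rle(run)
  run_len <- rep.int(rr$lengths, rr$lengths)
  sum(run & run_len >= config$mvpa_run_bout_minutes) +
    sum(walk & active_len >= config$mvpa_walk_bout_minutes)
}

#' Detect MVPA minutes for one day from minute samples
#'
#' Emulates the device's automated active-minute rule: a minute counts as
#' moderate-to-vigorous physical activity when the wearer runs (cadence at or
#' above the run threshold) for at least one minute, or walks (cadence between
#' the walk and run thresholds) within a maximal consecutive stretch of
#' walk-or-run minutes lasting at least ten minutes. Minutes absent from the
#' record are treated as idle and break bout continuity.
#'
#' @param minutes minute-sample data.frame for a single calendar day
#'   (minute-aligned timestamps, strictly increasing). Cadence is the minute's
#'   step count.
#' @param config a [wear_config()].
#' @return integer count of MVPA minutes.
#' @examples
#' day <- as.POSIXct("2020-02-17 10:00", tz = "UTC")
#' m <- data.frame(participant_id = "P01", timestamp = day + 60 * (0:9),
#'                 steps = 105L, motion_intensity = 2L)
#' detect_mvpa_minutes(m)  # 10: a full 10-minute walk bout
#' @export
detect_mvpa_minutes <- function(minutes, config = wear_config()) {
  if (nrow(minutes) == 0) return(0L)
  sec <- as.numeric(minutes$timestamp)
  ww_assert(all(sec %% 60 == 0), "minute samples must be minute-aligned")
  if (nrow(minutes) > 1) {
    ww_assert(all(diff(sec) > 0), "minute samples must be strictly increasing")
  }
  ww_assert(length(unique(ww_date(minutes$timestamp))) == 1L,
            "detect_mvpa_minutes expects a single calendar day")
  # expand onto a gap-free minute grid; absent minutes are idle
  m0 <- sec[1] %/% 60
  cad <- numeric(sec[length(sec)] %/% 60 - m0 + 1)
  cad[sec %/% 60 - m0 + 1] <- minutes$steps
  as.integer(mvpa_minutes_from_cadence(cad, config))
}

#' Summarize each observed day for one participant
#'
#' Combines the epoch sequence, wear mask and minute record into one row per
#' calendar day with any observed epoch: wear minutes inside the daily window,
#' total steps over worn epochs, MVPA minutes, weekend flag, and the validity
#' flag (`wear_minutes_window >= 480` and `total_steps >= 500` under the
#' defaults). Days with no observed epochs (e.g. the device was never synced)
#' are omitted rather than reported as invalid.
#'
#' @param epochs gap-free epoch data.frame for one participant.
#' @param mask logical wear mask aligned to `epochs`.
#' @param minutes the participant's minute samples (all days).
#' @param config a [wear_config()].
#' @return data.frame with columns `participant_id`, `date`,
#'   `wear_minutes_window`, `total_steps`, `mvpa_minutes`, `is_weekend`,
#'   `is_valid`.
#' @export
summarize_days <- function(epochs, mask, minutes, config = wear_config()) {
  ww_assert(length(mask) == nrow(epochs),
            "wear mask must align with the epoch sequence")
  if (nrow(epochs) == 0) {
    return(data.frame(participant_id = character(0),
                      date = as.Date(character(0)),
                      wear_minutes_window = integer(0),
                      total_steps = integer(0), mvpa_minutes = integer(0),
                      is_weekend = logical(0), is_valid = logical(0)))
  }
  pid <- epochs$participant_id[1]
  eday <- ww_date(epochs$epoch_start)
  observed <- tapply(epochs$n_minutes_observed > 0, eday, any)
  dates <- as.Date(names(observed)[observed])

  mod <- ww_min_of_day(epochs$epoch_start)
  w0 <- hhmm_to_minutes(config$window_start)
  w1 <- hhmm_to_minutes(config$window_end)
  in_win <- mod >= w0 & mod < w1

  mday <- ww_date(minutes$timestamp)
  out <- lapply(dates, function(d) {
    sel <- eday == d
    wear_min <- 15L * sum(mask & sel & in_win)
    steps <- sum(epochs$steps[sel & mask])
    mv <- detect_mvpa_minutes(minutes[mday == d, , drop = FALSE], config)
    data.frame(participant_id = pid, date = d,
               wear_minutes_window = wear_min,
               total_steps = as.integer(steps),
               mvpa_minutes = mv,
               is_weekend = is_weekend_date(d),
               is_valid = wear_min >= config$valid_day_min_wear_minutes &
                 steps >= config$valid_day_min_steps)
  })
  do.call(rbind, out)
}

#' Process one participant's minute record into day summaries
#'
#' Convenience wrapper: epoch aggregation, padding each calendar day to the
#' full 96-epoch grid, nonwear detection, and day summarisation.
#'
#' @param minutes validated minute-sample data.frame for one participant.
#' @param config a [wear_config()].
#' @return day-summary data.frame as from [summarize_days()].
#' @export
process_participant_days <- function(minutes, config = wear_config()) {
  epochs <- pad_epochs_to_days(aggregate_to_epochs(minutes))
  mask <- detect_nonwear(epochs, config)
  summarize_days(epochs, mask, minutes, config)
}
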