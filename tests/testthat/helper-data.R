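# small in-code fixture builders

DAY1 <- as.Date("2020-02-17")  # the default design's first Monday

is_weekend_date <- function(d) as.POSIXlt(as.Date(d))$wday %in% c(0L, 6L)

make_minutes <- function(start, steps, intensity = NULL, id = "P001") {
  if (is.null(intensity)) intensity <- ifelse(steps > 0, 2L, 1L)
  data.frame(participant_id = rep(id, length(steps)),
             timestamp = as.POSIXct(start, tz = "UTC") +
               60 * (seq_along(steps) - 1),
             steps = as.integer(steps),
             motion_intensity = as.integer(intensity))
}

make_epochs <- function(intensity, start = "2020-02-17 00:00:00",
                        steps = NULL, id = "P001") {
  if (is.null(steps)) steps <- ifelse(intensity > 0, 100L, 0L)
  data.frame(participant_id = rep(id, length(intensity)),
             epoch_start = as.POSIXct(start, tz = "UTC") +
               900 * (seq_along(intensity) - 1),
             steps = as.integer(steps),
             max_motion_intensity = as.integer(intensity),
             n_minutes_observed = rep(15L, length(intensity)))
}

make_day <- function(date, steps, mvpa = 0L, wear = 720L, id = "P001",
                     valid = NULL) {
  date <- as.Date(date)
  if (is.null(valid)) valid <- wear >= 480 && steps >= 500
  data.frame(participant_id = id, date = date,
             wear_minutes_window = as.integer(wear),
             total_steps = as.integer(steps), mvpa_minutes = as.integer(mvpa),
             is_weekend = is_weekend_date(date), is_valid = valid)
}

make_days <- function(...) do.call(rbind, list(...))

# balanced week-summary grid for model tests
make_week_grid <- function(n_participants, n_weeks = 8, closure_week = 5) {
  w <- expand.grid(participant_id = sprintf("P%03d", seq_len(n_participants)),
                   study_week = seq_len(n_weeks), stringsAsFactors = FALSE)
  w$period <- ifelse(w$study_week >= closure_week, "post", "pre")
  w$n_valid_weekdays <- 5L
  w$n_valid_weekend_days <- 2L
  w$is_valid_week <- TRUE
  w$steps_per_day <- NA_real_
  w$mvpa_min_per_day <- NA_real_
  w$mvpa_min_per_week <- NA_real_
  w
}
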