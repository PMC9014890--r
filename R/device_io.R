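# Device export IO: minute-level CSVs, epoch aggregation, summary tables,
# demographics. Minute files have columns timestamp,steps,motion_intensity
# (ISO-8601 timestamps, one row per observed minute; idle unworn minutes are
# simply absent).

RACE_LEVELS <- c("Black", "Hispanic/Latinx", "White", "Other/no response")
GENDER_LEVELS <- c("Male", "Female", "Other/no response")
INCOME_LEVELS <- c("<=1000", "1000-2000", "2000-3000", "3000-4000", ">=4000")
GROUP_LEVELS <- c("included", "excluded")

#' Read a per-participant minute-level device export
#'
#' Reads a CSV with columns `timestamp`, `steps`, `motion_intensity` into a
#' validated minute-sample data frame. Timestamps must be strictly increasing
#' (duplicates are rejected); steps and motion intensity must be non-negative
#' integers, with nonzero steps implying nonzero intensity. Gaps are preserved
#' as-is; nothing is imputed.
#'
#' @param path CSV file path.
#' @param id participant identifier; defaults to the file name without
#'   extension.
#' @return data.frame with columns `participant_id`, `timestamp` (POSIXct,
#'   wall-clock/UTC), `steps` (integer), `motion_intensity` (integer), sorted
#'   by timestamp.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("timestamp,steps,motion_intensity",
#'              "2020-02-17T09:00:00,12,2",
#'              "2020-02-17T09:01:00,0,1"), f)
#' read_minute_csv(f, id = "P01")
#' @export
read_minute_csv <- function(path, id = NULL) {
  ww_assert(file.exists(path), sprintf("file not found: %s", path),
            "wearweek_io_error")
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("timestamp", "steps", "motion_intensity")) {
    if (!col %in% names(df)) {
      ww_stop(sprintf("minute file %s is missing required column '%s'",
                      basename(path), col), "wearweek_format_error")
    }
  }
  ts <- ww_parse_time(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad)) {
    ww_stop(sprintf("unparseable timestamp at row %d: '%s'",
                    bad[1], df$timestamp[bad[1]]), "wearweek_validation_error")
  }
  validate_minute_samples(data.frame(
    participant_id = id,
    timestamp = ts,
    steps = df$steps,
    motion_intensity = df$motion_intensity,
    stringsAsFactors = FALSE
  ))
}

validate_minute_samples <- function(samples) {
  if (nrow(samples) > 1) {
    d <- diff(as.numeric(samples$timestamp))
    off <- which(d <= 0)
    if (length(off)) {
      what <- if (d[off[1]] == 0) "duplicate" else "non-increasing"
      ww_stop(sprintf("%s timestamp at row %d (%s)", what, off[1] + 1L,
                      ww_format_time(samples$timestamp[off[1] + 1L])),
              "wearweek_validation_error")
    }
  }
  neg <- which(samples$steps < 0 | samples$motion_intensity < 0)
  if (length(neg)) {
    ww_stop(sprintf("negative steps or motion_intensity at row %d", neg[1]),
            "wearweek_validation_error")
  }
  inc <- which(samples$steps > 0 & samples$motion_intensity == 0)
  if (length(inc)) {
    ww_stop(sprintf(
      "row %d has steps > 0 but motion_intensity == 0", inc[1]),
      "wearweek_validation_error")
  }
  samples$steps <- as.integer(samples$steps)
  samples$motion_intensity <- as.integer(samples$motion_intensity)
  samples
}

#' Write minute samples to a per-participant CSV
#'
#' Inverse of [read_minute_csv()]; the round trip is lossless.
#'
#' @param samples minute-sample data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_minute_csv <- function(samples, path) {
  out <- data.frame(
    timestamp = ww_format_time(samples$timestamp),
    steps = samples$steps,
    motion_intensity = samples$motion_intensity
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate minute samples to 15-minute epochs
#'
#' Bins minute samples onto the fixed clock-aligned 15-minute grid
#' (:00/:15/:30/:45, anchored at midnight). One epoch record is emitted for
#' every grid cell intersecting the observation span (first to last sample);
#' cells with no samples get zero steps, zero intensity and
#' `n_minutes_observed = 0`. Steps are summed and motion intensity maximised
#' within each epoch.
#'
#' @param samples validated minute-sample data.frame (sorted, unique
#'   timestamps).
#' @return data.frame with columns `participant_id`, `epoch_start` (POSIXct),
#'   `steps`, `max_motion_intensity`, `n_minutes_observed`.
#' @examples
#' m <- data.frame(participant_id = "P01",
#'                 timestamp = as.POSIXct("2020-02-17 09:00", tz = "UTC") +
#'                   60 * (0:14),
#'                 steps = 10L, motion_intensity = 2L)
#' aggregate_to_epochs(m)  # one epoch: steps 150, max intensity 2
#' @export
aggregate_to_epochs <- function(samples) {
  pid <- if (nrow(samples)) samples$participant_id[1] else character(0)
  if (nrow(samples) == 0) {
    return(data.frame(participant_id = character(0),
                      epoch_start = as.POSIXct(character(0), tz = "UTC"),
                      steps = integer(0), max_motion_intensity = integer(0),
                      n_minutes_observed = integer(0)))
  }
  samples <- validate_minute_samples(samples)
  cell <- as.numeric(samples$timestamp) %/% 900
  g0 <- cell[1]
  k <- as.integer(cell[length(cell)] - g0 + 1)
  i <- as.integer(cell - g0 + 1)
  steps <- integer(k)
  agg <- rowsum(samples$steps, i)
  steps[as.integer(rownames(agg))] <- as.integer(agg[, 1])
  mx <- integer(k)
  am <- tapply(samples$motion_intensity, i, max)
  mx[as.integer(names(am))] <- as.integer(am)
  data.frame(
    participant_id = pid,
    epoch_start = as.POSIXct((g0 + seq_len(k) - 1) * 900,
                             origin = "1970-01-01", tz = "UTC"),
    steps = steps,
    max_motion_intensity = mx,
    n_minutes_observed = tabulate(i, k)
  )
}

# pad an epoch sequence so every calendar day touched by the span carries its
# full 96-epoch grid; unobserved cells get zero steps/intensity
pad_epochs_to_days <- function(epochs) {
  if (nrow(epochs) == 0) return(epochs)
  day0 <- as.numeric(trunc(epochs$epoch_start[1], "days"))
  day1 <- as.numeric(trunc(epochs$epoch_start[nrow(epochs)], "days")) + 86400
  grid <- seq(day0, day1 - 900, by = 900)
  idx <- match(as.numeric(epochs$epoch_start), grid)
  out <- data.frame(
    participant_id = epochs$participant_id[1],
    epoch_start = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    steps = 0L, max_motion_intensity = 0L, n_minutes_observed = 0L
  )
  out$steps[idx] <- epochs$steps
  out$max_motion_intensity[idx] <- epochs$max_motion_intensity
  out$n_minutes_observed[idx] <- epochs$n_minutes_observed
  out
}

#' Write and read day-summary tables
#'
#' Day summaries are written as
#' `participant_id,date,wear_minutes_window,total_steps,mvpa_minutes,is_weekend,is_valid`;
#' the round trip is lossless.
#'
#' @param days day-summary data.frame from [summarize_days()].
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the data.frame (reader).
#' @export
write_day_summaries <- function(days, path) {
  out <- days
  out$date <- format(out$date)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_day_summaries
#' @export
read_day_summaries <- function(path) {
  ww_assert(file.exists(path), sprintf("file not found: %s", path),
            "wearweek_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character"))
  df$date <- as.Date(df$date)
  df
}

#' Write and read week-summary tables
#'
#' Week summaries are written with columns
#' `participant_id,study_week,period,steps_per_day,mvpa_min_per_day,mvpa_min_per_week,n_valid_weekdays,n_valid_weekend_days,is_valid_week`.
#' Real-valued outcomes are written at full precision; invalid weeks carry NA
#' outcomes.
#'
#' @param weeks week-summary data.frame from [summarize_weeks()].
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the data.frame (reader).
#' @export
write_week_summaries <- function(weeks, path) {
  write.csv(weeks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_week_summaries
#' @export
read_week_summaries <- function(path) {
  ww_assert(file.exists(path), sprintf("file not found: %s", path),
            "wearweek_io_error")
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(participant_id = "character"))
}

#' Read and write participant demographics
#'
#' Demographics tables have columns
#' `participant_id,group,race_ethnicity,gender,income_bracket` with closed
#' category sets (group: included/excluded; race/ethnicity: Black,
#' Hispanic/Latinx, White, Other/no response; gender: Male, Female, Other/no
#' response; income: five ordered monthly brackets). Membership is validated
#' on read.
#'
#' @param path CSV path.
#' @param demographics demographics data.frame.
#' @return the validated data.frame (reader) or `path` (writer, invisibly).
#' @export
read_demographics_csv <- function(path) {
  ww_assert(file.exists(path), sprintf("file not found: %s", path),
            "wearweek_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character"))
  validate_demographics(df)
}

#' @rdname read_demographics_csv
#' @export
write_demographics_csv <- function(demographics, path) {
  validate_demographics(demographics)
  write.csv(demographics, path, row.names = FALSE)
  invisible(path)
}

validate_demographics <- function(df) {
  need <- c("participant_id", "group", "race_ethnicity", "gender", "income_bracket")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ww_stop(sprintf("demographics table missing column '%s'", miss[1]),
            "wearweek_format_error")
  }
  ww_assert(!anyDuplicated(df$participant_id),
            "demographics: one record per participant required")
  chk <- list(group = GROUP_LEVELS, race_ethnicity = RACE_LEVELS,
              gender = GENDER_LEVELS, income_bracket = INCOME_LEVELS)
  for (col in names(chk)) {
    bad <- setdiff(unique(df[[col]]), chk[[col]])
    if (length(bad)) {
      ww_stop(sprintf("demographics: unknown %s category '%s'", col, bad[1]),
              "wearweek_validation_error")
    }
  }
  df
}
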