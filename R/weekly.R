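# Weekly aggregation: study-week assignment, weekday/weekend-weighted weekly
# values with the all-valid-days fallback, the >=1-valid-day week rule, and
# the pre/post participant inclusion criterion.

#' Assign study weeks and periods to day summaries
#'
#' Study week w covers days `[start + 7(w-1), start + 7w)`; weeks are
#' Monday-anchored 7-day blocks. The period is `"pre"` for weeks before the
#' design's closure week and `"post"` from the closure week onward.
#'
#' @param days day-summary data.frame with a `date` column.
#' @param design a [study_design()].
#' @return `days` with `study_week` (integer) and `period` (character) added.
#' @examples
#' des <- study_design("2020-02-17")
#' d <- data.frame(date = as.Date(c("2020-02-17", "2020-03-16")))
#' assign_study_weeks(d, des)[, c("date", "study_week", "period")]
#' @export
assign_study_weeks <- function(days, design) {
  off <- as.integer(days$date - design$study_start_date)
  bad <- which(off < 0 | off >= 7L * design$n_weeks)
  if (length(bad)) {
    ww_stop(sprintf("date %s lies outside the study span", days$date[bad[1]]),
            "wearweek_validation_error")
  }
  days$study_week <- off %/% 7L + 1L
  days$period <- ifelse(days$study_week >= design$closure_week, "post", "pre")
  days
}

#' Weekday/weekend-weighted weekly value
#'
#' Computes `(mean over valid weekdays x 5 + mean over valid weekend days x 2)
#' / 7` when the week has at least one valid weekday and one valid weekend
#' day; otherwise falls back to the unweighted mean over all valid days.
#'
#' @param values outcome values of the week's valid days.
#' @param is_weekend logical vector marking which values are weekend days.
#' @return the weighted (or fallback) weekly value.
#' @examples
#' weighted_weekly_value(c(7000, 3500), c(FALSE, TRUE))  # (7000*5+3500*2)/7
#' weighted_weekly_value(c(6000, 8000, 7000), rep(FALSE, 3))  # fallback: 7000
#' @export
weighted_weekly_value <- function(values, is_weekend) {
  ww_assert(length(values) == length(is_weekend),
            "values and is_weekend must align")
  if (length(values) == 0) {
    ww_stop("weighted weekly value requires at least one valid day",
            "wearweek_precondition_error")
  }
  wd <- values[!is_weekend]
  we <- values[is_weekend]
  if (length(wd) >= 1 && length(we) >= 1) {
    (mean(wd) * 5 + mean(we) * 2) / 7
  } else {
    mean(values)
  }
}

#' Summarize participant-weeks
#'
#' Aggregates day summaries to one row per participant and study week having
#' at least one observed day. A week is valid when it has at least one valid
#' day; weighted outcomes (steps/day and MVPA min/day via
#' [weighted_weekly_value()], over valid days only) are computed for valid
#' weeks and `NA` otherwise. MVPA minutes per week is exactly 7 x MVPA
#' minutes per day.
#'
#' @param days day-summary data.frame; `study_week`/`period` are added via
#'   [assign_study_weeks()] if absent.
#' @param design a [study_design()].
#' @return data.frame with columns `participant_id`, `study_week`, `period`,
#'   `steps_per_day`, `mvpa_min_per_day`, `mvpa_min_per_week`,
#'   `n_valid_weekdays`, `n_valid_weekend_days`, `is_valid_week`.
#' @export
summarize_weeks <- function(days, design) {
  if (!"study_week" %in% names(days)) days <- assign_study_weeks(days, design)
  if (nrow(days) == 0) {
    return(data.frame(participant_id = character(0), study_week = integer(0),
                      period = character(0), steps_per_day = numeric(0),
                      mvpa_min_per_day = numeric(0),
                      mvpa_min_per_week = numeric(0),
                      n_valid_weekdays = integer(0),
                      n_valid_weekend_days = integer(0),
                      is_valid_week = logical(0)))
  }
  pieces <- split(days, list(days$participant_id, days$study_week), drop = TRUE)
  out <- lapply(pieces, function(g) {
    v <- g[g$is_valid, , drop = FALSE]
    n_wd <- sum(!v$is_weekend)
    n_we <- sum(v$is_weekend)
    valid <- (n_wd + n_we) >= 1L
    if (valid) {
      spd <- weighted_weekly_value(v$total_steps, v$is_weekend)
      mpd <- weighted_weekly_value(v$mvpa_minutes, v$is_weekend)
    } else {
      spd <- NA_real_
      mpd <- NA_real_
    }
    data.frame(participant_id = g$participant_id[1],
               study_week = g$study_week[1], period = g$period[1],
               steps_per_day = spd, mvpa_min_per_day = mpd,
               mvpa_min_per_week = 7 * mpd,
               n_valid_weekdays = n_wd, n_valid_weekend_days = n_we,
               is_valid_week = valid)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$participant_id, out$study_week), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the pre/post participant inclusion criterion
#'
#' A participant is included when they have at least one valid week in the
#' pre period and at least one valid week in the post period.
#'
#' @param weeks week-summary data.frame from [summarize_weeks()].
#' @param design a [study_design()].
#' @return character vector of included participant ids, sorted.
#' @export
filter_participants <- function(weeks, design) {
  v <- weeks[weeks$is_valid_week, , drop = FALSE]
  pre <- unique(v$participant_id[v$study_week %in% design$pre_weeks])
  post <- unique(v$participant_id[v$study_week %in% design$post_weeks])
  sort(intersect(pre, post))
}
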