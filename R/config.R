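#' Wear-processing configuration
#'
#' Parameters governing nonwear detection, valid-day classification, and
#' bout-based MVPA minute detection. Defaults implement the device rules used
#' throughout the package: nonwear is any maximal run of at least
#' `nonwear_min_run_epochs` consecutive 15-minute epochs with zero maximum
#' motion intensity; a valid day has at least `valid_day_min_wear_minutes`
#' minutes of wear between `window_start` and `window_end` and at least
#' `valid_day_min_steps` steps; MVPA minutes are minutes run at cadence
#' `>= mvpa_run_cadence` (counted in bouts of at least `mvpa_run_bout_minutes`,
#' default every run minute) plus walk minutes (cadence in
#' `[mvpa_walk_cadence, mvpa_run_cadence)`) lying inside a maximal consecutive
#' run of walk-or-run minutes of length `>= mvpa_walk_bout_minutes`.
#'
#' @param nonwear_min_run_epochs minimum run of zero-intensity epochs counted
#'   as nonwear (epochs; default 3 = 45 minutes).
#' @param valid_day_min_wear_minutes minimum wear minutes inside the daily
#'   window for a valid day (default 480 = 8 h).
#' @param valid_day_min_steps minimum daily steps for a valid day (default 500).
#' @param window_start,window_end daily wear window, "HH:MM"; the window is
#'   half-open on epoch starts, so the defaults cover exactly 48 epochs.
#' @param mvpa_walk_cadence,mvpa_run_cadence cadence thresholds in steps/min
#'   separating idle/walk/run minutes (defaults 100 and 130).
#' @param mvpa_walk_bout_minutes minimum consecutive walk-or-run minutes for
#'   walk minutes to count as MVPA (default 10).
#' @param mvpa_run_bout_minutes minimum consecutive run minutes for run
#'   minutes to count (default 1, i.e. always).
#' @return a list of class `wear_config`.
#' @examples
#' wear_config()
#' wear_config(mvpa_walk_cadence = 110)
#' @export
wear_config <- function(nonwear_min_run_epochs = 3L,
                        valid_day_min_wear_minutes = 480L,
                        valid_day_min_steps = 500L,
                        window_start = "09:00",
                        window_end = "21:00",
                        mvpa_walk_cadence = 100,
                        mvpa_run_cadence = 130,
                        mvpa_walk_bout_minutes = 10L,
                        mvpa_run_bout_minutes = 1L) {
  cfg <- list(
    nonwear_min_run_epochs = as.integer(nonwear_min_run_epochs),
    valid_day_min_wear_minutes = as.integer(valid_day_min_wear_minutes),
    valid_day_min_steps = as.integer(valid_day_min_steps),
    window_start = window_start,
    window_end = window_end,
    mvpa_walk_cadence = mvpa_walk_cadence,
    mvpa_run_cadence = mvpa_run_cadence,
    mvpa_walk_bout_minutes = as.integer(mvpa_walk_bout_minutes),
    mvpa_run_bout_minutes = as.integer(mvpa_run_bout_minutes)
  )
  ww_assert(cfg$nonwear_min_run_epochs >= 1L, "nonwear_min_run_epochs must be >= 1")
  ww_assert(cfg$valid_day_min_wear_minutes >= 0L, "valid_day_min_wear_minutes must be >= 0")
  ww_assert(cfg$valid_day_min_steps >= 0L, "valid_day_min_steps must be >= 0")
  ww_assert(cfg$mvpa_walk_cadence < cfg$mvpa_run_cadence,
            "mvpa_walk_cadence must be below mvpa_run_cadence")
  ww_assert(cfg$mvpa_walk_bout_minutes >= 1L && cfg$mvpa_run_bout_minutes >= 1L,
            "bout lengths must be >= 1 minute")
  for (k in c("window_start", "window_end")) {
    ww_assert(grepl("^[0-2][0-9]:[0-5][0-9]$", cfg[[k]]),
              sprintf("%s must be 'HH:MM'", k))
  }
  structure(cfg, class = "wear_config")
}

hhmm_to_minutes <- function(x) {
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.integer(p[1]) * 60L + as.integer(p[2])
}

#' Study design: calendar anchors for an interrupted pre/post design
#'
#' Defines the study calendar as consecutive Monday-anchored 7-day blocks.
#' Study week w covers days `[start + 7(w-1), start + 7w)`; weeks before
#' `closure_week` form the pre period and weeks from `closure_week` onward the
#' post period.
#'
#' @param study_start_date first day of study week 1 (a Monday), `Date` or
#'   "YYYY-MM-DD".
#' @param n_weeks total number of study weeks (default 8).
#' @param closure_week first post-interruption study week (default 5).
#' @return a list of class `study_design` with fields `study_start_date`,
#'   `n_weeks`, `closure_week`, `pre_weeks`, `post_weeks`.
#' @examples
#' study_design("2020-02-17")
#' @export
study_design <- function(study_start_date, n_weeks = 8L, closure_week = 5L) {
  d <- as.Date(study_start_date)
  ww_assert(!is.na(d), "study_start_date must be a parseable date")
  ww_assert(as.POSIXlt(d)$wday == 1L, "study_start_date must be a Monday")
  n_weeks <- as.integer(n_weeks)
  closure_week <- as.integer(closure_week)
  ww_assert(n_weeks >= 2L, "n_weeks must be >= 2")
  ww_assert(closure_week >= 2L && closure_week <= n_weeks,
            "closure_week must lie in 2..n_weeks")
  structure(list(
    study_start_date = d,
    n_weeks = n_weeks,
    closure_week = closure_week,
    pre_weeks = seq_len(closure_week - 1L),
    post_weeks = seq.int(closure_week, n_weeks)
  ), class = "study_design")
}

#' Read a study design from a JSON or YAML config file
#'
#' The file must contain `study_start_date`, and may contain `n_weeks` and
#' `closure_week`; the result is validated by [study_design()].
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a `study_design` object.
#' @export
read_design_config <- function(path) {
  ww_assert(file.exists(path), sprintf("design config not found: %s", path),
            "wearweek_io_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  ww_assert(!is.null(raw$study_start_date),
            "design config must define study_start_date", "wearweek_format_error")
  study_design(raw$study_start_date,
               n_weeks = raw$n_weeks %||% 8L,
               closure_week = raw$closure_week %||% 5L)
}

write_design_config <- function(design, path) {
  jsonlite::write_json(list(
    study_start_date = as.character(design$study_start_date),
    n_weeks = design$n_weeks,
    closure_week = design$closure_week
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d weeks from %s; post period begins week %d\n",
              x$n_weeks, format(x$study_start_date), x$closure_week))
  invisible(x)
}
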