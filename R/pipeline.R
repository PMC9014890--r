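# End-to-end orchestration: minutes -> epochs -> wear -> days -> weeks ->
# inclusion -> mixed models -> results bundle.

#' Process a directory of minute files into day and week summaries
#'
#' Reads every `*.csv` minute file in `input_dir` (excluding the
#' `demographics.csv` sidecar), runs epoch aggregation, nonwear detection and
#' day summarisation per participant, assigns study weeks, and aggregates to
#' week summaries.
#'
#' @param input_dir directory of per-participant minute CSVs.
#' @param design a [study_design()] (or path handled by
#'   [read_design_config()]).
#' @param config a [wear_config()].
#' @return list with `days`, `weeks` and a `counts` list (participants read,
#'   observed days, valid days, valid weeks).
#' @export
process_cohort <- function(input_dir, design, config = wear_config()) {
  if (is.character(design)) design <- read_design_config(design)
  files <- list.files(input_dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!basename(files) %in% c("demographics.csv")]
  ww_assert(length(files) >= 1,
            sprintf("no minute files found in %s", input_dir),
            "wearweek_io_error")
  days <- do.call(rbind, lapply(files, function(f) {
    process_participant_days(read_minute_csv(f), config)
  }))
  days <- assign_study_weeks(days, design)
  weeks <- summarize_weeks(days, design)
  list(days = days, weeks = weeks,
       counts = list(participants_read = length(files),
                     observed_days = nrow(days),
                     valid_days = sum(days$is_valid),
                     valid_weeks = sum(weeks$is_valid_week)))
}

#' Fit both model families on week summaries and bundle results
#'
#' Applies the pre/post inclusion criterion, fits the period and categorical
#' study-week mixed models for both outcomes on the included participants'
#' valid weeks, and assembles the results bundle.
#'
#' @param weeks week-summary data.frame.
#' @param design a [study_design()].
#' @param out_dir optional output directory for the results bundle files.
#' @return list of class `pipeline_result` with `included` (ids),
#'   `period_models`, `weekly_models`, `results` (an `activity_results`),
#'   and `counts`.
#' @export
analyze_weeks <- function(weeks, design, out_dir = NULL) {
  included <- filter_participants(weeks, design)
  if (length(included) == 0) {
    ww_stop("no participants meet pre/post inclusion criterion",
            "wearweek_precondition_error")
  }
  wk <- weeks[weeks$participant_id %in% included, , drop = FALSE]
  outcomes <- c("steps_per_day", "mvpa_min_per_week")
  period_models <- lapply(outcomes, function(oc) fit_period_model(wk, oc))
  weekly_models <- lapply(outcomes, function(oc) fit_weekly_model(wk, oc))
  names(period_models) <- names(weekly_models) <- outcomes
  results <- summarize_results(period_models, weekly_models, design, out_dir)
  structure(list(included = included, period_models = period_models,
                 weekly_models = weekly_models, results = results,
                 counts = list(participants = length(unique(weeks$participant_id)),
                               included_participants = length(included),
                               modeled_weeks = sum(wk$is_valid_week))),
            class = "pipeline_result")
}

#' Run the full pipeline from minute files to the results bundle
#'
#' Composes [process_cohort()] and [analyze_weeks()], writes
#' `day_summaries.csv`, `week_summaries.csv` and the results bundle under
#' `out_dir`, and logs per-stage record counts via `message()`.
#'
#' @param input_dir directory of per-participant minute CSVs (optionally with
#'   `demographics.csv`).
#' @param out_dir output directory.
#' @param design a [study_design()] or a design config path; defaults to
#'   `design.json` inside `input_dir` when present.
#' @param config a [wear_config()].
#' @return the `pipeline_result`, invisibly, with `days`, `weeks` and merged
#'   stage `counts` attached.
#' @export
run_pipeline <- function(input_dir, out_dir, design = NULL,
                         config = wear_config()) {
  if (is.null(design)) {
    dj <- file.path(input_dir, "design.json")
    ww_assert(file.exists(dj),
              "design is NULL and no design.json found in input_dir",
              "wearweek_io_error")
    design <- read_design_config(dj)
  }
  if (is.character(design)) design <- read_design_config(design)
  proc <- process_cohort(input_dir, design, config)
  message(sprintf("participants read: %d", proc$counts$participants_read))
  message(sprintf("observed days: %d (valid: %d)",
                  proc$counts$observed_days, proc$counts$valid_days))
  message(sprintf("valid weeks: %d", proc$counts$valid_weeks))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_day_summaries(proc$days, file.path(out_dir, "day_summaries.csv"))
  write_week_summaries(proc$weeks, file.path(out_dir, "week_summaries.csv"))
  ana <- analyze_weeks(proc$weeks, design, out_dir)
  message(sprintf("included participants: %d",
                  ana$counts$included_participants))
  ana$days <- proc$days
  ana$weeks <- proc$weeks
  ana$counts <- c(proc$counts, ana$counts)
  invisible(ana)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d included participants, %d modeled weeks\n",
              x$counts$included_participants, x$counts$modeled_weeks))
  print(x$results)
  invisible(x)
}
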