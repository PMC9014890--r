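# Synthetic cohort generator: minute-level device records with the target
# study's structure (activity levels, abrupt post-closure reduction, imperfect
# wear, post-closure sync dropout) plus ground truth, so the whole pipeline
# and both model families are testable without raw device data.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the generator stands in for: 17
#' youths over 8 study weeks, about 8003 steps/day and 80.18 MVPA min/week
#' (11.45 min/day) before an abrupt closure at week 5, post/pre ratios 0.546
#' (steps) and 0.575 (MVPA), a daily wear probability of 0.75 (so roughly 5.2
#' valid days per week), and a 15% chance a participant stops syncing
#' post-closure. `pre_steps_mean` and `pre_mvpa_min_per_day` are the expected
#' weekday/weekend-weighted daily values; weekend days run at `weekend_ratio`
#' times the weekday level, so weekday means are solved internally to keep
#' the weighted expectation on target.
#'
#' @param n_participants cohort size (default 17).
#' @param n_weeks study length in weeks (default 8).
#' @param closure_week first post-closure week (default 5).
#' @param study_start_date Monday anchoring week 1 (default "2020-02-17").
#' @param pre_steps_mean expected weighted steps/day pre-closure (default 8003).
#' @param post_pre_ratio post/pre ratio of true step means, in (0, 1]
#'   (default 0.546).
#' @param pre_mvpa_min_per_day expected weighted MVPA min/day pre-closure
#'   (default 80.18 / 7).
#' @param mvpa_post_pre_ratio post/pre ratio of true MVPA means (default 0.575).
#' @param between_participant_sd between-participant SD of true daily steps
#'   (lognormal multipliers; default 1500).
#' @param within_participant_day_sd day-to-day SD of steps around the
#'   participant mean (default 1800).
#' @param mvpa_between_sd,mvpa_within_sd analogous SDs for MVPA min/day
#'   (defaults 3 and 3).
#' @param weekend_ratio weekend/weekday activity ratio (default 0.9).
#' @param wear_day_prob_pre,wear_day_prob_post probability a given day is a
#'   wear day (defaults 0.75, targeting ~5.2 valid days/week).
#' @param post_dropout_prob probability a participant stops producing data
#'   from the closure week onward (default 0.15).
#' @param walk_cadence_range,run_cadence_range cadence bands (steps/min) for
#'   generated walk and run bout minutes; defaults sit inside the default
#'   detection thresholds (walk 100, run 130).
#' @param seed integer seed driving a per-participant seed sequence.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 17L, n_weeks = 8L,
                             closure_week = 5L,
                             study_start_date = "2020-02-17",
                             pre_steps_mean = 8003,
                             post_pre_ratio = 0.546,
                             pre_mvpa_min_per_day = 80.18 / 7,
                             mvpa_post_pre_ratio = 0.575,
                             between_participant_sd = 1500,
                             within_participant_day_sd = 1800,
                             mvpa_between_sd = 3, mvpa_within_sd = 3,
                             weekend_ratio = 0.9,
                             wear_day_prob_pre = 0.75,
                             wear_day_prob_post = 0.75,
                             post_dropout_prob = 0.15,
                             walk_cadence_range = c(102, 128),
                             run_cadence_range = c(132, 160),
                             seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_weeks = as.integer(n_weeks),
              closure_week = as.integer(closure_week),
              study_start_date = as.Date(study_start_date),
              pre_steps_mean = pre_steps_mean,
              post_pre_ratio = post_pre_ratio,
              pre_mvpa_min_per_day = pre_mvpa_min_per_day,
              mvpa_post_pre_ratio = mvpa_post_pre_ratio,
              between_participant_sd = between_participant_sd,
              within_participant_day_sd = within_participant_day_sd,
              mvpa_between_sd = mvpa_between_sd,
              mvpa_within_sd = mvpa_within_sd,
              weekend_ratio = weekend_ratio,
              wear_day_prob_pre = wear_day_prob_pre,
              wear_day_prob_post = wear_day_prob_post,
              post_dropout_prob = post_dropout_prob,
              walk_cadence_range = walk_cadence_range,
              run_cadence_range = run_cadence_range,
              seed = as.integer(seed))
  ww_assert(cfg$n_participants >= 1, "n_participants must be >= 1")
  for (k in c("wear_day_prob_pre", "wear_day_prob_post", "post_dropout_prob")) {
    ww_assert(cfg[[k]] >= 0 && cfg[[k]] <= 1,
              sprintf("%s must lie in [0, 1]", k))
  }
  for (k in c("post_pre_ratio", "mvpa_post_pre_ratio", "weekend_ratio")) {
    ww_assert(cfg[[k]] > 0 && cfg[[k]] <= 1,
              sprintf("%s must lie in (0, 1]", k))
  }
  ww_assert(cfg$pre_steps_mean > 0 && cfg$pre_mvpa_min_per_day >= 0,
            "activity means must be positive")
  for (k in c("between_participant_sd", "within_participant_day_sd",
              "mvpa_between_sd", "mvpa_within_sd")) {
    ww_assert(cfg[[k]] >= 0, sprintf("%s must be >= 0", k))
  }
  for (k in c("walk_cadence_range", "run_cadence_range")) {
    ww_assert(length(cfg[[k]]) == 2 && cfg[[k]][1] <= cfg[[k]][2] &&
                cfg[[k]][1] > 0, sprintf("%s must be an increasing pair", k))
  }
  structure(cfg, class = "synthetic_config")
}

# solve the weekday-level mean whose (5 wd + 2 we)/7 weighting hits `target`
weekday_mean_for <- function(target, weekend_ratio) {
  7 * target / (5 + 2 * weekend_ratio)
}

# location parameter mu such that E[max(0, N(mu, sd))] equals `target`:
# day values are zero-censored normal draws, and naive mu = target would
# inflate the realized mean whenever target is within a few sd of zero
mu_for_censored_mean <- function(target, sd) {
  if (sd <= 0 || target / sd > 6) return(target)
  f <- function(mu) mu * stats::pnorm(mu / sd) + sd * stats::dnorm(mu / sd) - target
  stats::uniroot(f, lower = -6 * sd, upper = target + sd, tol = 1e-9)$root
}

# memoised vector version (targets repeat across days)
adjust_locations <- function(targets, sd) {
  u <- unique(targets)
  a <- vapply(u, mu_for_censored_mean, numeric(1), sd = sd)
  a[match(targets, u)]
}

# participant-level truth: lognormal multipliers with unit mean
participant_truth <- function(cfg) {
  sb <- cfg$between_participant_sd / cfg$pre_steps_mean
  sm <- if (cfg$pre_mvpa_min_per_day > 0) {
    cfg$mvpa_between_sd / cfg$pre_mvpa_min_per_day
  } else 0
  list(steps_mult = exp(rnorm(1, 0, sb) - sb^2 / 2),
       mvpa_mult = exp(rnorm(1, 0, sm) - sm^2 / 2))
}

# one worn day's minute record: a waking wear block with random gaps, one
# consecutive walk bout (>= 10 min) plus scattered run minutes realising the
# day's MVPA target, light-cadence minutes realising the residual step
# target, and zero-step idle worn minutes (intensity 1) elsewhere
build_day_minutes <- function(date, steps_target, mvpa_target, cfg) {
  block0 <- sample(420:510, 1)   # 07:00-08:30
  block1 <- sample(1290:1380, 1) # 21:30-23:00
  mins <- block0:(block1 - 1L)
  worn <- rep(TRUE, length(mins))
  for (g in seq_len(sample(0:2, 1))) {
    glen <- sample(20:70, 1)
    gstart <- sample(seq_len(length(mins) - glen), 1)
    worn[gstart:(gstart + glen - 1L)] <- FALSE
  }
  mins <- mins[worn]
  n <- length(mins)
  steps <- integer(n)
  intensity <- rep(1L, n)

  # split the MVPA target into one walk bout and always-counting run minutes
  M <- max(0L, as.integer(round(mvpa_target)))
  wb <- cfg$mvpa_walk_bout_minutes %||% 10L
  if (M < wb) {
    n_walk <- 0L
    n_run <- M
  } else {
    n_run <- as.integer(round(0.2 * M))
    n_walk <- M - n_run
    if (n_walk < wb) {
      n_walk <- wb
      n_run <- M - wb
    }
  }
  taken <- logical(n)
  if (n_walk > 0L) {
    # longest contiguous worn segment hosts the walk bout
    newseg <- c(TRUE, diff(mins) != 1L)
    lens <- tabulate(cumsum(newseg))
    starts <- which(newseg)
    best <- which.max(lens)
    n_walk <- min(n_walk, lens[best])
    off <- sample.int(lens[best] - n_walk + 1L, 1)
    idx <- starts[best] + off - 1L + 0:(n_walk - 1L)
    steps[idx] <- sample(cfg$walk_cadence_range[1]:cfg$walk_cadence_range[2],
                         n_walk, replace = TRUE)
    intensity[idx] <- 2L
    taken[idx] <- TRUE
  }
  if (n_run > 0L) {
    free <- which(!taken)
    idx <- sample(free, min(n_run, length(free)))
    steps[idx] <- sample(cfg$run_cadence_range[1]:cfg$run_cadence_range[2],
                         length(idx), replace = TRUE)
    intensity[idx] <- 3L
    taken[idx] <- TRUE
  }

  resid <- max(0L, as.integer(round(steps_target)) - sum(steps))
  free <- which(!taken)
  if (resid > 0L && length(free)) {
    cad <- sample(30:95, length(free), replace = TRUE)
    cs <- cumsum(cad)
    j <- which(cs >= resid)[1]
    if (is.na(j)) {
      j <- length(free)         # not enough free minutes; undershoot slightly
    } else {
      cad[j] <- resid - if (j > 1) cs[j - 1L] else 0L
    }
    use <- sample(free, j)
    keep <- cad[seq_len(j)] > 0L
    steps[use[keep]] <- cad[seq_len(j)][keep]
  }

  data.frame(
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + 60 * mins,
    steps = steps, motion_intensity = intensity
  )
}

#' Generate a synthetic minute-level cohort with ground truth
#'
#' For each participant, draws true daily activity levels (lognormal
#' participant multipliers around the configured means, dropping to the
#' configured post/pre ratios from the closure week), realises each wear day
#' as a minute record (wear block with random gaps, a consecutive walk bout
#' plus run minutes matching the MVPA target, light-cadence minutes matching
#' the step target, zero-step worn idle minutes), skips non-wear days
#' entirely, and — with probability `post_dropout_prob` — stops a
#' participant's record at the closure week to mimic sync dropout. One global
#' seed drives a per-participant seed sequence, so output is fully
#' reproducible and individual participants can be regenerated.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional directory; when given, writes one
#'   `<participant_id>.csv` minute file per participant, `demographics.csv`,
#'   `ground_truth.json` and `design.json`.
#' @return a list with `minutes` (named list of minute-sample data.frames),
#'   `demographics`, `ground_truth` (per-participant true means, dropout and
#'   wear realisation), and `design` (a [study_design()]).
#' @export
generate_cohort <- function(config = synthetic_config(), out_dir = NULL) {
  cfg <- if (inherits(config, "synthetic_config")) config else
    do.call(synthetic_config, config)
  design <- study_design(cfg$study_start_date, cfg$n_weeks, cfg$closure_week)
  set.seed(cfg$seed)
  pseeds <- sample.int(.Machine$integer.max - 1L, cfg$n_participants)
  dseed <- sample.int(.Machine$integer.max - 1L, 1)
  ids <- sprintf("P%03d", seq_len(cfg$n_participants))

  wd_steps <- weekday_mean_for(cfg$pre_steps_mean, cfg$weekend_ratio)
  wd_mvpa <- weekday_mean_for(cfg$pre_mvpa_min_per_day, cfg$weekend_ratio)
  dates <- seq(cfg$study_start_date, by = "day",
               length.out = 7L * cfg$n_weeks)
  weeks <- as.integer(dates - cfg$study_start_date) %/% 7L + 1L
  weekend <- is_weekend_date(dates)
  post <- weeks >= cfg$closure_week

  minutes <- vector("list", cfg$n_participants)
  truth <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    set.seed(pseeds[i])
    tr <- participant_truth(cfg)
    dropout <- runif(1) < cfg$post_dropout_prob
    day_means <- wd_steps * tr$steps_mult *
      ifelse(weekend, cfg$weekend_ratio, 1) *
      ifelse(post, cfg$post_pre_ratio, 1)
    day_mvpa <- wd_mvpa * tr$mvpa_mult *
      ifelse(weekend, cfg$weekend_ratio, 1) *
      ifelse(post, cfg$mvpa_post_pre_ratio, 1)
    wear_p <- ifelse(post, cfg$wear_day_prob_post, cfg$wear_day_prob_pre)
    worn_day <- runif(length(dates)) < wear_p
    if (dropout) worn_day[post] <- FALSE
    mu_steps <- adjust_locations(day_means, cfg$within_participant_day_sd)
    mu_mvpa <- adjust_locations(day_mvpa, cfg$mvpa_within_sd)

    recs <- vector("list", sum(worn_day))
    k <- 0L
    for (d in which(worn_day)) {
      k <- k + 1L
      s_target <- max(0, rnorm(1, mu_steps[d], cfg$within_participant_day_sd))
      m_target <- max(0, rnorm(1, mu_mvpa[d], cfg$mvpa_within_sd))
      recs[[k]] <- build_day_minutes(dates[d], s_target, m_target, cfg)
    }
    dm <- if (k > 0) do.call(rbind, recs) else
      data.frame(timestamp = as.POSIXct(character(0), tz = "UTC"),
                 steps = integer(0), motion_intensity = integer(0))
    dm <- cbind(participant_id = rep(ids[i], nrow(dm)), dm)
    minutes[[i]] <- dm
    truth[[i]] <- list(
      participant_id = ids[i],
      steps_mult = tr$steps_mult, mvpa_mult = tr$mvpa_mult,
      true_steps_per_day_pre = cfg$pre_steps_mean * tr$steps_mult,
      true_steps_per_day_post = cfg$pre_steps_mean * tr$steps_mult *
        cfg$post_pre_ratio,
      true_mvpa_min_per_day_pre = cfg$pre_mvpa_min_per_day * tr$mvpa_mult,
      true_mvpa_min_per_day_post = cfg$pre_mvpa_min_per_day * tr$mvpa_mult *
        cfg$mvpa_post_pre_ratio,
      dropout = dropout,
      worn_dates = as.character(dates[worn_day])
    )
  }
  names(minutes) <- ids
  demographics <- generate_demographics(cfg$n_participants, seed = dseed)
  demographics$participant_id <- ids

  out <- list(minutes = minutes, demographics = demographics,
              ground_truth = setNames(truth, ids), design = design)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids) {
      write_minute_csv(minutes[[id]], file.path(out_dir, paste0(id, ".csv")))
    }
    write_demographics_csv(demographics, file.path(out_dir, "demographics.csv"))
    jsonlite::write_json(out$ground_truth,
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_design_config(design, file.path(out_dir, "design.json"))
  }
  out
}

#' Generate a synthetic demographics table
#'
#' Samples the closed demographic categories from the marginal proportions of
#' the emulated cohort (race/ethnicity 7:8:2:0 Black : Hispanic/Latinx :
#' White : Other; gender 7:10:0 Male : Female : Other; five income brackets
#' 4:4:5:2:2), deterministically per seed.
#'
#' @param n number of participants.
#' @param seed optional integer seed.
#' @param group group label for all rows (default "included").
#' @return a validated demographics data.frame.
#' @export
generate_demographics <- function(n, seed = NULL, group = "included") {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = group,
    race_ethnicity = sample(RACE_LEVELS, n, replace = TRUE,
                            prob = c(7, 8, 2, 0) / 17),
    gender = sample(GENDER_LEVELS, n, replace = TRUE, prob = c(7, 10, 0) / 17),
    income_bracket = sample(INCOME_LEVELS, n, replace = TRUE,
                            prob = c(4, 4, 5, 2, 2) / 17)
  )
  validate_demographics(df)
}

#' Simulate week-level summaries directly
#'
#' Week-level counterpart of [generate_cohort()] for statistical calibration
#' of the mixed models: draws each participant-week's valid weekday/weekend
#' day counts and day-level outcome values from the same truth structure
#' (lognormal participant multipliers, post/pre ratios, wear probability,
#' all-or-nothing post dropout) and aggregates them with
#' [weighted_weekly_value()], skipping minute-level synthesis. Useful when
#' hundreds of simulated cohorts are needed.
#'
#' @param config a [synthetic_config()].
#' @return a week-summary data.frame in the [summarize_weeks()] schema
#'   (valid weeks only).
#' @export
simulate_week_summaries <- function(config = synthetic_config()) {
  cfg <- if (inherits(config, "synthetic_config")) config else
    do.call(synthetic_config, config)
  set.seed(cfg$seed)
  pseeds <- sample.int(.Machine$integer.max - 1L, cfg$n_participants)
  ids <- sprintf("P%03d", seq_len(cfg$n_participants))
  wd_steps <- weekday_mean_for(cfg$pre_steps_mean, cfg$weekend_ratio)
  wd_mvpa <- weekday_mean_for(cfg$pre_mvpa_min_per_day, cfg$weekend_ratio)
  rows <- list()
  for (i in seq_len(cfg$n_participants)) {
    set.seed(pseeds[i])
    tr <- participant_truth(cfg)
    dropout <- runif(1) < cfg$post_dropout_prob
    for (w in seq_len(cfg$n_weeks)) {
      post <- w >= cfg$closure_week
      if (post && dropout) next
      p <- if (post) cfg$wear_day_prob_post else cfg$wear_day_prob_pre
      worn <- runif(7) < p
      if (!any(worn)) next
      weekendness <- c(rep(FALSE, 5), TRUE, TRUE)[worn]
      ratio_s <- if (post) cfg$post_pre_ratio else 1
      ratio_m <- if (post) cfg$mvpa_post_pre_ratio else 1
      mu_s <- adjust_locations(
        wd_steps * tr$steps_mult * ratio_s *
          ifelse(weekendness, cfg$weekend_ratio, 1),
        cfg$within_participant_day_sd)
      mu_m <- adjust_locations(
        wd_mvpa * tr$mvpa_mult * ratio_m *
          ifelse(weekendness, cfg$weekend_ratio, 1),
        cfg$mvpa_within_sd)
      vs <- pmax(0, rnorm(sum(worn), mu_s, cfg$within_participant_day_sd))
      vm <- pmax(0, rnorm(sum(worn), mu_m, cfg$mvpa_within_sd))
      mpd <- weighted_weekly_value(vm, weekendness)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids[i], study_week = w,
        period = if (post) "post" else "pre",
        steps_per_day = weighted_weekly_value(vs, weekendness),
        mvpa_min_per_day = mpd, mvpa_min_per_week = 7 * mpd,
        n_valid_weekdays = sum(!weekendness),
        n_valid_weekend_days = sum(weekendness),
        is_valid_week = TRUE)
    }
  }
  do.call(rbind, rows)
}
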