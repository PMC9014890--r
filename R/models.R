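# Mixed-effects comparison of weekly activity outcomes, estimated marginal
# means, percent-change summaries, and the chi-square demographic comparison.

#' Fit the pre/post mixed-effects model for a weekly outcome
#'
#' Fits, by restricted maximum likelihood, a linear mixed model of the weekly
#' outcome on period (pre/post), adjusted for the number of valid weekday and
#' weekend wear days in the week, with a random intercept per participant to
#' account for the nesting of weeks within participants:
#'
#' \deqn{y_{ij} = \beta_0 + \beta_1\,\mathrm{post}_{ij} +
#'   \beta_2\,\mathrm{wd}_{ij} + \beta_3\,\mathrm{we}_{ij} + b_i +
#'   \varepsilon_{ij}}
#'
#' with \eqn{b_i \sim N(0, \sigma_u^2)} and
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2)}. Only valid weeks contribute;
#' missing weeks are handled by REML on the available data (no imputation).
#' F tests use Satterthwaite denominator degrees of freedom; estimated
#' marginal means are computed at the sample means of the covariates.
#'
#' @param weeks week-summary data.frame from [summarize_weeks()] (invalid
#'   weeks are dropped internally).
#' @param outcome `"steps_per_day"` or `"mvpa_min_per_week"`.
#' @return an object of class `activity_mixed_fit`; see
#'   [print.activity_mixed_fit()]. Fields include `fixed_effects`, `f_tests`,
#'   `estimated_means` (level, mean, 95% CI), `fit_method` (`"REML"`),
#'   `df_method` (`"Satterthwaite"`), `n_participants`,
#'   `n_week_observations`, and the underlying `lmerMod` in `$fit`.
#' @seealso [fit_weekly_model()] for the categorical study-week model.
#' @export
fit_period_model <- function(weeks,
                             outcome = c("steps_per_day", "mvpa_min_per_week")) {
  outcome <- match.arg(outcome)
  dat <- model_data(weeks, outcome)
  dat$period <- factor(dat$period, levels = c("pre", "post"))
  both <- tapply(dat$period, dat$participant_id,
                 function(p) all(c("pre", "post") %in% p))
  if (sum(both, na.rm = TRUE) < 2L) {
    ww_stop("need >= 2 participants with valid weeks in both periods",
            "wearweek_precondition_error")
  }
  fit_activity_model(dat, outcome, "period")
}

#' Fit the categorical study-week mixed-effects model
#'
#' Same structure as [fit_period_model()] with the pre/post term replaced by
#' study week as a categorical fixed effect (reference = the earliest week
#' present), yielding per-week estimated marginal means with 95% CIs for
#' trajectory plots.
#'
#' @inheritParams fit_period_model
#' @return an `activity_mixed_fit` whose `estimated_means` has one row per
#'   study week.
#' @export
fit_weekly_model <- function(weeks,
                             outcome = c("steps_per_day", "mvpa_min_per_week")) {
  outcome <- match.arg(outcome)
  dat <- model_data(weeks, outcome)
  if (length(unique(dat$study_week)) < 2L) {
    ww_stop("need >= 2 study weeks represented among valid weeks",
            "wearweek_precondition_error")
  }
  dat$study_week <- factor(dat$study_week,
                           levels = sort(unique(dat$study_week)))
  fit_activity_model(dat, outcome, "study_week")
}

model_data <- function(weeks, outcome) {
  dat <- weeks[weeks$is_valid_week & !is.na(weeks[[outcome]]), , drop = FALSE]
  if (nrow(dat) == 0) {
    ww_stop("no valid weeks to model", "wearweek_precondition_error")
  }
  dat$participant_id <- factor(dat$participant_id)
  dat
}

fit_activity_model <- function(dat, outcome, time_term) {
  # zero-variance outcome: the REML problem is degenerate (all variance
  # components zero) and downstream machinery is numerically fragile there,
  # but the answer is exact: every effect is zero and every mean equals the
  # constant. Return it directly with a diagnostic warning.
  if (stats::var(dat[[outcome]]) == 0) {
    return(degenerate_fit(dat, outcome, time_term))
  }
  fml <- as.formula(paste(
    outcome, "~", time_term,
    "+ n_valid_weekdays + n_valid_weekend_days + (1 | participant_id)"))
  quiet_fit <- function(engine) {
    withCallingHandlers(
      tryCatch(engine(fml, data = dat, REML = TRUE),
               error = function(e) e),
      message = function(m) invokeRestart("muffleMessage"),
      warning = function(w) {
        if (grepl("failed to converge", conditionMessage(w))) {
          # lme4's gradient check; heuristic (it false-positives on
          # zero-variance data), so surface it as a classed diagnostic warning
          warning(warningCondition(
            sprintf("mixed-model convergence check: %s", conditionMessage(w)),
            class = "wearweek_convergence_warning"))
        }
        invokeRestart("muffleWarning")
      }
    )
  }
  # lmerTest supplies Satterthwaite df; its refit can fail on degenerate
  # (zero-variance) data where plain lme4 still succeeds, so fall back to
  # lme4 with asymptotic inference there
  df_method <- "Satterthwaite"
  fit <- quiet_fit(lmerTest::lmer)
  if (inherits(fit, "error")) {
    df_method <- "asymptotic"
    fit <- quiet_fit(lme4::lmer)
    if (inherits(fit, "error")) {
      ww_stop(sprintf("mixed-model fit failed: %s", conditionMessage(fit)),
              "wearweek_model_error")
    }
  }
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
    ww_stop(sprintf("mixed-model optimizer failed (code %d): %s",
                    fit@optinfo$conv$opt,
                    paste(unlist(fit@optinfo$message), collapse = "; ")),
            "wearweek_model_error")
  }
  if (lme4::isSingular(fit)) {
    warning(warningCondition(
      "mixed-model fit is singular (a variance component is zero)",
      class = "wearweek_singular_fit"))
  }
  fe <- lme4::fixef(fit)
  # vcov can fail on fully degenerate (zero-variance) fits
  fe_se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(fit)))),
                    error = function(e) rep(NA_real_, length(fe)))
  if (df_method == "Satterthwaite") {
    an <- suppressWarnings(suppressMessages(anova(fit, type = 3)))
    f_tests <- data.frame(term = rownames(an), f_value = an[["F value"]],
                          df_num = an[["NumDF"]], df_den = an[["DenDF"]],
                          p_value = an[["Pr(>F)"]], row.names = NULL)
  } else {
    an <- suppressWarnings(suppressMessages(anova(fit)))
    f_tests <- data.frame(term = rownames(an), f_value = an[["F value"]],
                          df_num = an[["npar"]], df_den = NA_real_,
                          p_value = NA_real_, row.names = NULL)
  }
  em <- suppressMessages(
    emmeans::emmeans(fit, specs = time_term,
                     lmer.df = if (df_method == "Satterthwaite")
                       "satterthwaite" else "asymptotic"))
  ems <- as.data.frame(summary(em, level = 0.95))
  estimated_means <- data.frame(level = as.character(ems[[time_term]]),
                                mean = ems$emmean, se = ems$SE, df = ems$df,
                                ci_lo = ems$lower.CL, ci_hi = ems$upper.CL)
  structure(list(
    outcome = outcome, time_term = time_term, fit = fit,
    fixed_effects = data.frame(term = names(fe), estimate = unname(fe),
                               se = unname(fe_se)),
    f_tests = f_tests, estimated_means = estimated_means,
    fit_method = "REML", df_method = "Satterthwaite",
    n_participants = nlevels(droplevels(dat$participant_id)),
    n_week_observations = nrow(dat), formula = fml
  ), class = "activity_mixed_fit")
}

degenerate_fit <- function(dat, outcome, time_term) {
  warning(warningCondition(
    "outcome is constant: returning the exact degenerate fit (all effects zero)",
    class = "wearweek_singular_fit"))
  v <- dat[[outcome]][1]
  lev <- if (time_term == "period") c("pre", "post") else
    levels(dat$study_week)
  terms <- c("(Intercept)", paste0(time_term, lev[-1]),
             "n_valid_weekdays", "n_valid_weekend_days")
  structure(list(
    outcome = outcome, time_term = time_term, fit = NULL,
    fixed_effects = data.frame(term = terms,
                               estimate = c(v, rep(0, length(terms) - 1L)),
                               se = c(0, rep(0, length(terms) - 1L))),
    f_tests = data.frame(term = time_term, f_value = NA_real_,
                         df_num = length(lev) - 1L, df_den = NA_real_,
                         p_value = NA_real_),
    estimated_means = data.frame(level = lev, mean = v, se = 0, df = NA_real_,
                                 ci_lo = v, ci_hi = v),
    fit_method = "REML", df_method = "degenerate",
    n_participants = nlevels(droplevels(dat$participant_id)),
    n_week_observations = nrow(dat),
    formula = NULL
  ), class = "activity_mixed_fit")
}

#' @export
print.activity_mixed_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects model (%s) for %s by %s\n",
              x$fit_method, x$outcome, x$time_term))
  cat(sprintf("  %d participants, %d participant-week observations\n",
              x$n_participants, x$n_week_observations))
  ft <- x$f_tests[x$f_tests$term == x$time_term, ]
  if (nrow(ft) == 1) {
    cat(sprintf("  %s: F(%d, %.1f) = %.2f, p = %.4g (%s df)\n", x$time_term,
                ft$df_num, ft$df_den, ft$f_value, ft$p_value, x$df_method))
  }
  cat("Estimated marginal means (95% CI):\n")
  m <- x$estimated_means
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-6s %10.2f  [%.2f, %.2f]\n",
                m$level[i], m$mean[i], m$ci_lo[i], m$ci_hi[i]))
  }
  invisible(x)
}

#' @export
summary.activity_mixed_fit <- function(object, ...) {
  print(object)
  cat("\nFixed effects:\n")
  print(object$fixed_effects, row.names = FALSE)
  cat("\nF tests (type III, Satterthwaite):\n")
  print(object$f_tests, row.names = FALSE)
  invisible(object)
}

#' @export
coef.activity_mixed_fit <- function(object, ...) {
  setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' @export
predict.activity_mixed_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$fit, ...) else
    predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.activity_mixed_fit <- function(object, ...) {
  stats::residuals(object$fit, ...)
}

#' Plot estimated means with 95% confidence intervals
#'
#' Draws the model's estimated marginal means against period or study week
#' with error bars spanning the 95% CIs.
#'
#' @param x an `activity_mixed_fit`.
#' @param ylab y-axis label; defaults to the outcome name.
#' @param ... passed to [graphics::plot()].
#' @return the `estimated_means` data.frame, invisibly.
#' @export
plot.activity_mixed_fit <- function(x, ylab = x$outcome, ...) {
  m <- x$estimated_means
  at <- seq_len(nrow(m))
  graphics::plot(at, m$mean, ylim = range(m$ci_lo, m$ci_hi), xaxt = "n",
                 xlab = if (x$time_term == "period") "Period" else "Study week",
                 ylab = ylab, pch = 19, ...)
  graphics::axis(1, at = at, labels = m$level)
  graphics::arrows(at, m$ci_lo, at, m$ci_hi, angle = 90, code = 3,
                   length = 0.05)
  graphics::lines(at, m$mean, lty = 2)
  invisible(m)
}

#' Percent change between period means
#'
#' `100 * (post - pre) / pre`, rounded to one decimal with ties away from
#' zero — the convention used for reported percent-change figures.
#'
#' @param pre_mean pre-period mean, must be positive.
#' @param post_mean post-period mean, must be non-negative.
#' @return signed percent change, one decimal place.
#' @examples
#' percent_change(8003, 4366)    # -45.4
#' percent_change(80.18, 46.13)  # -42.5
#' @export
percent_change <- function(pre_mean, post_mean) {
  ww_assert(is.numeric(pre_mean) && pre_mean > 0,
            "pre_mean must be > 0", "wearweek_domain_error")
  ww_assert(is.numeric(post_mean) && post_mean >= 0,
            "post_mean must be >= 0", "wearweek_domain_error")
  round_half_away(100 * (post_mean - pre_mean) / pre_mean, 1)
}

#' Chi-square comparison of demographics by inclusion status
#'
#' Pearson chi-square test (no continuity correction) on the inclusion-status
#' by category cross-tabulation for one demographic variable. Categories with
#' zero total count across both groups are dropped before the test, so
#' structurally empty categories do not inflate the degrees of freedom.
#'
#' @param included,excluded demographics data.frames (see
#'   [read_demographics_csv()]) for the two groups.
#' @param variable `"race_ethnicity"`, `"gender"`, or `"income_bracket"`.
#' @return a list of class `contingency_result`: `statistic`, `df`,
#'   `p_value`, `table` (the counts used).
#' @export
compare_demographics <- function(included, excluded,
                                 variable = c("race_ethnicity", "gender",
                                              "income_bracket")) {
  variable <- match.arg(variable)
  levels <- switch(variable, race_ethnicity = RACE_LEVELS,
                   gender = GENDER_LEVELS, income_bracket = INCOME_LEVELS)
  tab <- rbind(
    included = table(factor(included[[variable]], levels = levels)),
    excluded = table(factor(excluded[[variable]], levels = levels))
  )
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    ww_stop("contingency table is degenerate (needs >= 2 rows and columns)",
            "wearweek_precondition_error")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), table = tab,
                 variable = variable),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square for %s: X^2 = %.3f, df = %d, p = %.3g\n",
              x$variable, x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

#' Assemble the results bundle from fitted models
#'
#' Builds the pre/post results table (means, SEs, percent change, F test per
#' outcome) and the per-week estimated-means table, optionally writing
#' `results_table.csv`, `weekly_means.csv`, `fig_steps.png` and
#' `fig_mvpa.png` under `out_dir`.
#'
#' @param period_models named list of `activity_mixed_fit` objects from
#'   [fit_period_model()], one per outcome.
#' @param weekly_models named list from [fit_weekly_model()], same outcomes.
#' @param design a [study_design()].
#' @param out_dir optional output directory.
#' @return a list of class `activity_results` with `results_table` and
#'   `weekly_means` data.frames.
#' @export
summarize_results <- function(period_models, weekly_models, design,
                              out_dir = NULL) {
  rows <- lapply(period_models, function(m) {
    em <- m$estimated_means
    pre <- em[em$level == "pre", ]
    post <- em[em$level == "post", ]
    ft <- m$f_tests[m$f_tests$term == "period", ]
    data.frame(outcome = m$outcome,
               pre_mean = pre$mean, pre_se = pre$se,
               post_mean = post$mean, post_se = post$se,
               pct_change = percent_change(pre$mean, post$mean),
               f_value = ft$f_value, df_num = ft$df_num, df_den = ft$df_den,
               p_value = ft$p_value)
  })
  results_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  wk <- lapply(weekly_models, function(m) {
    em <- m$estimated_means
    data.frame(outcome = m$outcome, study_week = as.integer(em$level),
               mean = em$mean, ci_lo = em$ci_lo, ci_hi = em$ci_hi)
  })
  weekly_means <- do.call(rbind, c(wk, list(make.row.names = FALSE)))
  res <- structure(list(results_table = results_table,
                        weekly_means = weekly_means, design = design),
                   class = "activity_results")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results_table, file.path(out_dir, "results_table.csv"),
              row.names = FALSE)
    write.csv(weekly_means, file.path(out_dir, "weekly_means.csv"),
              row.names = FALSE)
    figs <- c(steps_per_day = "fig_steps.png", mvpa_min_per_week = "fig_mvpa.png")
    for (oc in names(weekly_models)) {
      fn <- figs[[weekly_models[[oc]]$outcome]] %||% paste0("fig_", oc, ".png")
      grDevices::png(file.path(out_dir, fn), width = 900, height = 600)
      plot(weekly_models[[oc]])
      grDevices::dev.off()
    }
  }
  res
}

#' @export
print.activity_results <- function(x, ...) {
  cat("Pre/post results:\n")
  print(x$results_table, row.names = FALSE, digits = 6)
  invisible(x)
}
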