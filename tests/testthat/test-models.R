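test_that("percent change reproduces the worked pre/post examples", {
  expect_identical(percent_change(8003, 4366), -45.4)
  expect_identical(percent_change(80.18, 46.13), -42.5)
  expect_identical(percent_change(123.4, 123.4), 0)
  expect_error(percent_change(0, 10), class = "wearweek_domain_error")
})

test_that("percent change is scale-invariant and sign-antisymmetric", {
  set.seed(9)
  for (rep in 1:50) {
    a <- runif(1, 1, 1e4); b <- runif(1, 1, 1e4); k <- runif(1, 0.1, 50)
    expect_identical(percent_change(k * a, k * b), percent_change(a, b))
    if (abs(a - b) > 1e-6) {
      expect_identical(sign(percent_change(a, b)), -sign(percent_change(b, a)))
    }
  }
  # reporting convention: ties round away from zero
  expect_identical(round_half_away(0.05, 1), 0.1)
  expect_identical(round_half_away(-0.05, 1), -0.1)
  expect_identical(round_half_away(100 * 10 / 17), 59)
  expect_identical(round_half_away(100 * 15 / 17), 88)
})

test_that("chi-square comparison matches the textbook formula and drops empty categories", {
  rec <- function(n_m, n_f, group) {
    data.frame(participant_id = sprintf("%s%03d", group, seq_len(n_m + n_f)),
               group = group,
               race_ethnicity = "Black",
               gender = rep(c("Male", "Female"), c(n_m, n_f)),
               income_bracket = "<=1000")
  }
  # perfect homogeneity
  r0 <- compare_demographics(rec(10, 10, "included"), rec(10, 10, "excluded"),
                             "gender")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # the emulated cohort's gender table (Other category empty, hence dropped)
  r1 <- compare_demographics(rec(7, 10, "included"), rec(28, 39, "excluded"),
                             "gender")
  tab <- rbind(c(7, 10), c(28, 39))
  expect_equal(r1$statistic, oracle_chisq(tab), tolerance = 1e-12)
  expect_equal(r1$df, 1L)
  expect_equal(dim(r1$table), c(2L, 2L))

  set.seed(12)
  for (rep in 1:30) {
    inc <- rec(sample(2:30, 1), sample(2:30, 1), "included")
    exc <- rec(sample(2:30, 1), sample(2:30, 1), "excluded")
    r <- compare_demographics(inc, exc, "gender")
    expect_equal(r$statistic, oracle_chisq(r$table), tolerance = 1e-10)
    expect_equal(r$df, (nrow(r$table) - 1L) * (ncol(r$table) - 1L))
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }

  # one remaining category -> degenerate
  one <- rec(5, 0, "included"); one$gender <- "Male"
  two <- rec(5, 0, "excluded"); two$gender <- "Male"
  expect_error(compare_demographics(one, two, "gender"),
               class = "wearweek_precondition_error")
})

test_that("period model on balanced covariate-constant data reduces to raw period means", {
  set.seed(31)
  w <- make_week_grid(6)
  shift <- ifelse(w$period == "post", -3000, 0)
  w$steps_per_day <- 8000 + shift + rnorm(nrow(w), 0, 50)
  # near-noise-free data legitimately triggers the singular-fit diagnostic
  m <- suppressWarnings(fit_period_model(w, "steps_per_day"))
  raw <- tapply(w$steps_per_day, w$period, mean)
  em <- setNames(m$estimated_means$mean, m$estimated_means$level)
  expect_equal(em[["pre"]], raw[["pre"]], tolerance = 1e-6)
  expect_equal(em[["post"]], raw[["post"]], tolerance = 1e-6)
  # every estimated mean lies inside its own CI
  expect_true(all(m$estimated_means$ci_lo <= m$estimated_means$mean &
                    m$estimated_means$mean <= m$estimated_means$ci_hi))
  ft <- m$f_tests[m$f_tests$term == "period", ]
  expect_gt(ft$df_den, 0)
  expect_equal(m$fit_method, "REML")
})

test_that("degenerate constant-outcome input yields a zero period effect", {
  w <- make_week_grid(4)
  w$steps_per_day <- 6000
  m <- suppressWarnings(fit_period_model(w, "steps_per_day"))
  expect_equal(unname(coef(m)["periodpost"]), 0, tolerance = 1e-8)
  expect_equal(m$estimated_means$mean[1], m$estimated_means$mean[2],
               tolerance = 1e-8)
})

test_that("model preconditions are enforced", {
  w <- make_week_grid(4)
  w$steps_per_day <- rnorm(nrow(w), 8000, 100)
  expect_error(fit_period_model(w[w$period == "pre", ], "steps_per_day"),
               class = "wearweek_precondition_error")
  expect_error(fit_weekly_model(w[w$study_week == 1, ], "steps_per_day"),
               class = "wearweek_precondition_error")
  expect_error(fit_period_model(w[0, ], "steps_per_day"),
               class = "wearweek_precondition_error")
})

test_that("weekly model recovers known per-week means and the injected change point", {
  set.seed(77)
  w <- make_week_grid(8)
  true_means <- c(8000, 8100, 7900, 8050, 4300, 4400, 4350, 4250)
  w$steps_per_day <- true_means[w$study_week] + rnorm(nrow(w), 0, 1e-4)
  m <- suppressWarnings(fit_weekly_model(w, "steps_per_day"))
  expect_equal(m$estimated_means$level, as.character(1:8))
  expect_equal(m$estimated_means$mean, true_means, tolerance = 1e-6)
  # the drop lands between weeks 4 and 5
  drops <- diff(m$estimated_means$mean)
  expect_equal(which.min(drops), 4L)
  expect_lt(drops[4], -3000)
})

test_that("the results bundle is internally consistent and written to disk", {
  set.seed(55)
  cfg <- synthetic_config(n_participants = 12, seed = 19)
  w <- simulate_week_summaries(cfg)
  des <- study_design(cfg$study_start_date, cfg$n_weeks, cfg$closure_week)
  out <- withr::local_tempdir()
  ana <- analyze_weeks(w, des, out_dir = out)
  rt <- ana$results$results_table
  expect_setequal(rt$outcome, c("steps_per_day", "mvpa_min_per_week"))
  expect_equal(names(rt), c("outcome", "pre_mean", "pre_se", "post_mean",
                            "post_se", "pct_change", "f_value", "df_num",
                            "df_den", "p_value"))
  for (i in seq_len(nrow(rt))) {
    expect_identical(rt$pct_change[i],
                     percent_change(rt$pre_mean[i], rt$post_mean[i]))
  }
  wm <- ana$results$weekly_means
  for (oc in names(ana$weekly_models)) {
    em <- ana$weekly_models[[oc]]$estimated_means
    sub <- wm[wm$outcome == oc, ]
    expect_equal(sub$mean, em$mean)
    expect_equal(sub$ci_lo, em$ci_lo)
    expect_equal(sub$study_week, as.integer(em$level))
  }
  expect_true(all(file.exists(file.path(out, c(
    "results_table.csv", "weekly_means.csv", "fig_steps.png", "fig_mvpa.png")))))
  # plotted series equals the weekly model's estimated means
  grDevices::png(withr::local_tempfile(fileext = ".png"))
  pd <- plot(ana$weekly_models$steps_per_day)
  grDevices::dev.off()
  expect_equal(pd$mean, ana$weekly_models$steps_per_day$estimated_means$mean)
})
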