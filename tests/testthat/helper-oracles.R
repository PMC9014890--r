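# Independent brute-force oracles, deliberately written with different
# algorithms than the package internals (explicit scans and window
# enumeration rather than run-length encoding).

# maximal-run scanner: worn unless inside a maximal zero-run of >= min_run
oracle_nonwear <- function(intensity, min_run = 3) {
  n <- length(intensity)
  worn <- rep(TRUE, n)
  i <- 1L
  while (i <= n) {
    if (intensity[i] == 0) {
      j <- i
      while (j < n && intensity[j + 1L] == 0) j <- j + 1L
      if (j - i + 1L >= min_run) worn[i:j] <- FALSE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  worn
}

# window enumerator: a walk minute counts iff some all-active window of
# exactly `bout` consecutive minutes contains it; run minutes always count
oracle_mvpa <- function(cadence, walk = 100, run = 130, bout = 10) {
  n <- length(cadence)
  is_run <- cadence >= run
  is_walk <- cadence >= walk & cadence < run
  active <- is_run | is_walk
  count <- is_run
  if (n >= bout) {
    for (i in which(is_walk)) {
      for (s in max(1L, i - bout + 1L):min(i, n - bout + 1L)) {
        if (all(active[s:(s + bout - 1L)])) {
          count[i] <- TRUE
          break
        }
      }
    }
  }
  sum(count)
}

# direct two-branch weekly arithmetic
oracle_weighted <- function(values, weekend) {
  wd <- values[!weekend]
  we <- values[weekend]
  if (length(wd) > 0 && length(we) > 0) {
    (sum(wd) / length(wd) * 5 + sum(we) / length(we) * 2) / 7
  } else {
    sum(values) / length(values)
  }
}

# textbook Pearson statistic
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# per-cell recomputation of epoch aggregates by filtering raw minutes
oracle_epochs <- function(minutes) {
  sec <- as.numeric(minutes$timestamp)
  g0 <- 900 * (min(sec) %/% 900)
  g1 <- 900 * (max(sec) %/% 900)
  starts <- seq(g0, g1, by = 900)
  out <- data.frame(epoch_start = as.POSIXct(starts, origin = "1970-01-01",
                                             tz = "UTC"),
                    steps = NA_integer_, max_motion_intensity = NA_integer_,
                    n_minutes_observed = NA_integer_)
  for (k in seq_along(starts)) {
    inside <- sec >= starts[k] & sec < starts[k] + 900
    out$steps[k] <- sum(minutes$steps[inside])
    out$max_motion_intensity[k] <-
      if (any(inside)) max(minutes$motion_intensity[inside]) else 0L
    out$n_minutes_observed[k] <- sum(inside)
  }
  out
}

# calendar walk: advance one day at a time, bumping the week every 7th day
oracle_study_week <- function(date, start) {
  wk <- 1L
  d <- start
  count <- 0L
  while (d < date) {
    d <- d + 1
    count <- count + 1L
    if (count %% 7L == 0L) wk <- wk + 1L
  }
  wk
}
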