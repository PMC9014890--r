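# internal helpers shared across modules

ww_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "wearweek_error")))
}

ww_assert <- function(cond, msg, class = "wearweek_validation_error") {
  if (!isTRUE(cond)) ww_stop(msg, class)
  invisible(TRUE)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.5 -> 1, -0.5 -> -1),
#' the convention used for reported percent figures. Base `round()` rounds
#' ties to even, which disagrees on exact half-values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_away(2.5)      # 3, where round(2.5) is 2
#' round_half_away(-42.45, 1)
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# parse ISO-8601-ish timestamps as wall-clock time; UTC avoids DST ambiguity.
# The canonical "%Y-%m-%dT%H:%M:%S" form is tried in one vectorised pass;
# only rows it cannot parse fall back to the slower multi-format path.
ww_parse_time <- function(x) {
  out <- .POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", x)
  if (any(iso)) {
    # minute files repeat few distinct dates; parse each date once and add
    # the time-of-day arithmetically
    xi <- x[iso]
    ds <- substr(xi, 1, 10)
    ud <- unique(ds)
    base <- as.numeric(as.POSIXct(ud, tz = "UTC", format = "%Y-%m-%d"))
    sec <- base[match(ds, ud)] +
      3600 * as.integer(substr(xi, 12, 13)) +
      60 * as.integer(substr(xi, 15, 16)) +
      as.integer(substr(xi, 18, 19))
    out[iso] <- sec
  }
  na <- is.na(out)
  if (any(na)) {
    alt <- suppressWarnings(tryCatch(
      as.POSIXct(x[na], tz = "UTC", tryFormats = c(
        "%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")),
      error = function(e) as.POSIXct(rep(NA_character_, sum(na)), tz = "UTC")))
    out[na] <- alt
  }
  out
}

ww_format_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

ww_date <- function(x) as.Date(x, tz = "UTC")

# minutes past midnight of a POSIXct vector
ww_min_of_day <- function(x) {
  lt <- as.POSIXlt(x, tz = "UTC")
  lt$hour * 60L + lt$min
}

is_weekend_date <- function(d) {
  w <- as.POSIXlt(d)$wday
  w == 0L | w == 6L
}
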