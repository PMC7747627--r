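#' Parse a timestamp at minute resolution
#'
#' Timestamps throughout the package are timezone-naive local clock time
#' (the controller schedules itself by the wall clock); they are stored as
#' `POSIXct` in UTC so no daylight-saving arithmetic is ever applied.
#'
#' @param x character vector, `"YYYY-MM-DD HH:MM"` (seconds optional).
#' @return `POSIXct` vector (UTC).
#' @export
tent_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M"))
  if (anyNA(out) && !anyNA(x)) stop("unparseable timestamp(s): ",
                                    paste(x[is.na(out)], collapse = ", "))
  out
}

#' Format a timestamp as ISO-8601 at minute resolution (no offset)
#' @param t POSIXct vector.
#' @return character vector.
#' @export
format_tent_time <- function(t) format(t, "%Y-%m-%d %H:%M", tz = "UTC")

## minute of day (0..1439) for a POSIXct
minute_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour * 60L + lt$min
}

## parse "HH:MM" to minute of day
parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-2]?[0-9]):([0-5][0-9])$", x))[[1]]
  if (length(m) != 3L) stop("invalid clock time: ", x)
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23L) stop("invalid clock time: ", x)
  h * 60L + mi
}

#' Is a timestamp inside a clock window (possibly crossing midnight)?
#'
#' The window is half-open: the start minute is inside, the end minute is
#' outside, so `in_clock_window(t, "19:00", "06:00")` is `FALSE` at exactly
#' 06:00.
#'
#' @param t POSIXct vector.
#' @param start,end `"HH:MM"` strings.
#' @return logical vector.
#' @export
in_clock_window <- function(t, start, end) {
  m <- minute_of_day(t)
  s <- parse_clock(start); e <- parse_clock(end)
  if (s == e) return(rep(TRUE, length(m)))    # degenerate: full day
  if (s < e) m >= s & m < e else m >= s | m < e
}

#' Round half away from zero
#'
#' Plain decimal rounding as printed in agronomy tables (R's [round()] uses
#' banker's rounding, which disagrees on exact halves).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

## internal: stopifnot-style check with a readable message
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
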