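#' Weekly discretisation of calendar dates
#'
#' The analysis runs on a weekly clock: every date is mapped to an integer
#' week index counted from a fixed origin date (the first day of week 0).
#' Weeks are 7-day blocks starting on the origin's weekday, so choosing a
#' Monday origin gives ISO-style Monday-start weeks. All stages of the
#' pipeline share one origin, which makes state tables, covariate windows and
#' simulation output line up exactly.
#'
#' @param date a `Date` vector (or anything coercible via [as.Date()]).
#' @param week_origin the date that starts week 0.
#' @return `week_index()`: integer week numbers. `week_start()`,
#'   `week_midpoint()`: `Date` vectors (midpoint = day 4 of the 7-day block).
#' @examples
#' week_index(as.Date("2007-04-16") + 0:13, as.Date("2007-01-01"))
#' @export
week_index <- function(date, week_origin) {
  date <- as.Date(date)
  week_origin <- as.Date(week_origin)
  as.integer(floor(as.numeric(date - week_origin) / 7))
}

#' @rdname week_index
#' @param week integer week index.
#' @export
week_start <- function(week, week_origin) {
  as.Date(week_origin) + 7L * as.integer(week)
}

#' @rdname week_index
#' @export
week_midpoint <- function(week, week_origin) {
  week_start(week, week_origin) + 3L
}
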