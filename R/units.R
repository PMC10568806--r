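#' Time-unit conversions
#'
#' The canonical internal time unit throughout the package is the day.
#' Months convert at 30.4375 days and years at 365.25 days, so that
#' 12 months equal exactly one year and clinical inputs quoted in weeks,
#' months or years land on one consistent scale.
#'
#' @param x numeric vector of durations.
#' @return numeric vector on the target scale.
#' @examples
#' months_to_days(16.5)
#' days_to_years(365.25)
#' @name time-units
NULL

#' @rdname time-units
#' @export
months_to_days <- function(x) x * 30.4375

#' @rdname time-units
#' @export
days_to_months <- function(x) x / 30.4375

#' @rdname time-units
#' @export
years_to_days <- function(x) x * 365.25

#' @rdname time-units
#' @export
days_to_years <- function(x) x / 365.25

`%||%` <- function(a, b) if (is.null(a)) b else a
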