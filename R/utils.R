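#' Round half away from zero
#'
#' Fixed-point rounding with halves rounded up (away from zero), the rule used
#' for all printed percentages. Base R's `round()` rounds half to even, which
#' would print 0.125 as 0.12 rather than 0.13.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(c(0.125, 11.955), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total, formatted by the reporting rounding rule
#'
#' @param a numerator count (vectorized).
#' @param total denominator; must be a single positive number.
#' @return numeric percentage rounded half-up to 2 decimals (e.g. 14.86).
#' @examples
#' pt_percent(197, 16355)
#' @export
pt_percent <- function(a, total) {
  stopifnot(length(total) == 1L, is.finite(total), total > 0)
  round_half_up(100 * a / total, 2)
}

# "2021Q3" -> first day of the quarter
quarter_start <- function(q) {
  y <- as.integer(substr(q, 1L, 4L))
  n <- as.integer(substr(q, 6L, 6L))
  as.Date(sprintf("%d-%02d-01", y, (n - 1L) * 3L + 1L))
}

# exclusive end: first day of the following quarter
quarter_end <- function(q) {
  y <- as.integer(substr(q, 1L, 4L))
  n <- as.integer(substr(q, 6L, 6L))
  y2 <- ifelse(n == 4L, y + 1L, y)
  n2 <- ifelse(n == 4L, 1L, n + 1L)
  as.Date(sprintf("%d-%02d-01", y2, (n2 - 1L) * 3L + 1L))
}

date_to_quarter <- function(d) {
  ifelse(is.na(d), NA_character_,
         sprintf("%sQ%d", format(d, "%Y"),
                 (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L))
}

#' Sequence of quarter labels
#'
#' @param from,to quarter labels like `"2021Q1"` (inclusive).
#' @return character vector of consecutive quarter labels.
#' @examples
#' quarter_seq("2023Q3", "2024Q2")
#' @export
quarter_seq <- function(from, to) {
  stopifnot(grepl("^\\d{4}Q[1-4]$", from), grepl("^\\d{4}Q[1-4]$", to))
  idx <- function(q) as.integer(substr(q, 1, 4)) * 4L + as.integer(substr(q, 6, 6)) - 1L
  i <- seq(idx(from), idx(to))
  sprintf("%dQ%d", i %/% 4L, i %% 4L + 1L)
}

pv_log <- function(fmt, ...) message(sprintf(paste0("[pvsignal] ", fmt), ...))
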