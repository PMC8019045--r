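# Shared helpers: year-month arithmetic, validation messaging.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Year-month helpers
#'
#' Months are represented throughout as `"YYYY-MM"` strings. `date_month()`
#' maps dates to their month, `month_seq()` enumerates the months covering a
#' date span, and `month_shift()` adds whole months.
#'
#' @param x a `Date` vector (`date_month`) or `"YYYY-MM"` string(s).
#' @param from,to `Date` or `"YYYY-MM"` bounds, inclusive.
#' @param k integer number of months to add (may be negative).
#' @return character vector of `"YYYY-MM"` months.
#' @examples
#' date_month(as.Date("2017-08-28"))
#' month_seq("2017-08", "2017-11")
#' month_shift("2018-12", 2)
#' @export
date_month <- function(x) format(as.Date(x), "%Y-%m")

#' @rdname date_month
#' @export
month_seq <- function(from, to) {
  from <- month_first_day(from)
  to <- month_first_day(to)
  if (from > to) stop("`from` month is after `to` month", call. = FALSE)
  format(seq(from, to, by = "month"), "%Y-%m")
}

#' @rdname date_month
#' @export
month_shift <- function(x, k) {
  d <- month_first_day(x)
  format(seq(d, by = paste(k, "month"), length.out = 2L)[2L], "%Y-%m")
}

month_first_day <- function(x) {
  if (inherits(x, "Date")) {
    as.Date(format(x, "%Y-%m-01"))
  } else {
    as.Date(paste0(as.character(x), "-01"))
  }
}

days_in_month <- function(ym) {
  first <- month_first_day(ym)
  nxt <- seq(first, by = "1 month", length.out = 2L)[2L]
  as.integer(nxt - first)
}

is_year_month <- function(x) {
  grepl("^\\d{4}-(0[1-9]|1[0-2])$", as.character(x))
}

# z-score with population SD; constant input is flagged by returning NAs.
z_pop <- function(x) {
  mu <- mean(x)
  sd_p <- sqrt(mean((x - mu)^2))
  if (sd_p == 0) return(rep(NA_real_, length(x)))
  (x - mu) / sd_p
}

# population coefficient of variation
cv_pop <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2)) / mu
}

# parse "HH:MM"; returns minutes since midnight or NA
time_minutes <- function(x) {
  ok <- grepl("^\\d{1,2}:\\d{2}$", x)
  out <- rep(NA_real_, length(x))
  parts <- strsplit(x[ok], ":", fixed = TRUE)
  out[ok] <- vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 1)
  out
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}
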