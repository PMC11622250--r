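#' Parse FAERS partial date stamps
#'
#' FAERS date fields are digit strings of length 8 (`YYYYMMDD`), 6 (`YYYYMM`)
#' or 4 (`YYYY`).  Anything else is treated as undefined; nothing is imputed.
#' A month outside 1--12 or a day outside 1--31 also yields an undefined date.
#'
#' @param x character vector of raw date stamps.
#' @return A data.frame with integer columns `year`, `month`, `day`; a
#'   component is `NA` when absent, and all three are `NA` when the stamp is
#'   unparseable.
#' @examples
#' parse_partial_date(c("20191115", "201911", "2019", "0", ""))
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)
  digits <- !is.na(x) & grepl("^[0-9]+$", x)
  nc <- nchar(x)

  full <- digits & nc == 8L
  ym   <- digits & nc == 6L
  yo   <- digits & nc == 4L

  year[full | ym | yo] <- as.integer(substr(x[full | ym | yo], 1L, 4L))
  month[full | ym] <- as.integer(substr(x[full | ym], 5L, 6L))
  day[full] <- as.integer(substr(x[full], 7L, 8L))

  bad_month <- !is.na(month) & (month < 1L | month > 12L)
  bad_day <- !is.na(day) & (day < 1L | day > 31L)
  bad <- bad_month | bad_day
  year[bad] <- month[bad] <- day[bad] <- NA_integer_

  data.frame(year = year, month = month, day = day)
}

# Numeric sort key for dedup ordering: full dates dominate, partial dates are
# padded with zeros, unparseable stamps sort before everything (-Inf).
partial_date_key <- function(x) {
  p <- parse_partial_date(x)
  key <- ifelse(is.na(p$year), -Inf,
                p$year * 10000 +
                  ifelse(is.na(p$month), 0, p$month) * 100 +
                  ifelse(is.na(p$day), 0, p$day))
  key
}

# Days since 1970-01-01 for complete 8-digit stamps, NA otherwise (including
# calendar-invalid dates such as Feb 30).
partial_date_days <- function(x) {
  p <- parse_partial_date(x)
  full <- !is.na(p$day)
  out <- rep(NA_real_, length(x))
  if (any(full)) {
    d <- as.Date(sprintf("%04d-%02d-%02d", p$year[full], p$month[full], p$day[full]),
                 format = "%Y-%m-%d")
    out[full] <- as.numeric(d)
  }
  out
}

# Inverse of partial_date_days for the generator: Date -> "YYYYMMDD".
days_to_stamp <- function(d) format(as.Date(d, origin = "1970-01-01"), "%Y%m%d")
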