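#' @importFrom rlang .data abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile rbinom rlnorm rnorm rpois runif setNames uniroot
#' @importFrom utils head
NULL

# FAERS dates come as 8-digit YYYYMMDD, 6-digit YYYYMM or 4-digit YYYY.
# Partial dates keep their year (for report-year summaries) but yield NA at
# day resolution, so no day is ever fabricated.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x %||% character(0)))
  x[is.na(x) | x == ""] <- NA_character_
  digits <- !is.na(x) & grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
  bad <- !is.na(x) & !digits
  year <- rep(NA_integer_, length(x))
  date <- rep(as.Date(NA), length(x))
  precision <- rep(NA_character_, length(x))
  if (any(digits)) {
    d <- x[digits]
    nc <- nchar(d)
    yr <- suppressWarnings(as.integer(substr(d, 1, 4)))
    full <- nc == 8L
    dt <- rep(as.Date(NA), length(d))
    dt[full] <- as.Date(d[full], format = "%Y%m%d")  # invalid day/month -> NA
    year[digits] <- yr
    date[digits] <- dt
    precision[digits] <- ifelse(nc == 8L & !is.na(dt), "day",
                         ifelse(nc == 6L, "month",
                         ifelse(nc == 4L, "year", "invalid")))
  }
  if (any(bad)) precision[bad] <- "invalid"
  tibble(raw = x, date = date, year = year, precision = precision)
}

# FAERS-documented age unit codes; anything else is treated as unknown and
# the age is left absent rather than guessed.
age_to_years <- function(age, unit) {
  a <- suppressWarnings(as.numeric(age))
  u <- toupper(trimws(as.character(unit)))
  out <- dplyr::case_when(
    is.na(a) ~ NA_real_,
    u == "YR" ~ a,
    u == "MON" ~ a / 12,
    u == "DY" ~ a / 365.25,
    u == "DEC" ~ a * 10,
    .default = NA_real_
  )
  out[!is.na(out) & (out < 0 | out > 130)] <- NA_real_
  out
}

# Trim, collapse internal whitespace; optionally case-fold for lookups.
normalize_term <- function(x, fold = TRUE) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  if (fold) toupper(x) else x
}

# Drug-name normalisation: uppercase, strip punctuation to spaces so that
# trailing dots, slashes and bracketed salts do not defeat matching.
normalize_drug_name <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Percentages from category counts
#'
#' The percentage arithmetic used throughout the descriptive summaries:
#' `100 * count / denominator`, rounded to 2 decimals. Exposed so printed
#' summary tables can be re-checked from their counts alone.
#'
#' @param counts Non-negative integer vector of category counts.
#' @param denominator Denominator; defaults to `sum(counts)` (the
#'   sum-of-categories rule).
#' @return Numeric vector of percentages rounded to 2 decimals.
#' @export
#' @examples
#' categorical_percent(c(1853, 24, 33))
categorical_percent <- function(counts, denominator = sum(counts)) {
  stopifnot(is.numeric(counts), denominator > 0)
  round(100 * counts / denominator, 2)
}

round2 <- function(x) round(x, 2)

seq_id <- function(prefix, n, width = 9) {
  sprintf("%s%0*d", prefix, width, seq_len(n))
}
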