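# Calendar arithmetic for infant-age windows.
#
# All period bookkeeping is done in whole days with "six months" meaning
# calendar-month addition: an infant born 2010-01-01 has its first window
# run through 2010-06-30.  Month addition rolls back to the last day of the
# month when the target day does not exist (Jan 31 + 1 month -> Feb 28/29).

#' Add whole calendar months to a date
#'
#' Calendar-month addition with end-of-month rollback, the convention used
#' for all infant-age windows in this package.
#'
#' @param x a `Date` vector.
#' @param n integer number of months (scalar).
#' @return a `Date` vector.
#' @examples
#' add_months(as.Date("2010-01-01"), 6)   # 2010-07-01
#' add_months(as.Date("2010-01-31"), 1)   # 2010-02-28
#' @export
add_months <- function(x, n) {
  lubridate::add_with_rollback(as.Date(x), lubridate::period(month = n))
}

#' Six-month infant-age bin of a calendar date
#'
#' Infancy up to 3.5 years is divided into seven half-open six-month bins:
#' bin 0 covers \[0, 6) months of age, bin 6 covers \[36, 42) months.  Dates
#' at or beyond 42 months of age fall outside infancy and return `NA`.
#'
#' @param birth_date infant birth date(s) (`Date`, scalar or same length as
#'   `date`).
#' @param date calendar date(s) to classify.
#' @param bin_months bin width in calendar months (default 6).
#' @param n_bins number of bins (default 7).
#' @return integer vector of bin indices in `0:(n_bins-1)`, `NA` when the
#'   date is past infancy.
#' @examples
#' age_bin_of(as.Date("2010-01-01"), as.Date("2010-07-01"))  # 1
#' @export
age_bin_of <- function(birth_date, date, bin_months = 6L, n_bins = 7L) {
  birth_date <- as.Date(birth_date)
  date <- as.Date(date)
  if (length(birth_date) == 1L) birth_date <- rep(birth_date, length(date))
  if (length(date) == 1L) date <- rep(date, length(birth_date))
  if (length(birth_date) != length(date)) {
    abort("`birth_date` and `date` must have compatible lengths.")
  }
  bad <- !is.na(date) & !is.na(birth_date) & date < birth_date
  if (any(bad)) {
    abort(paste0("`date` precedes `birth_date` for ", sum(bad), " element(s)."))
  }
  acc <- integer(length(date))
  for (k in seq_len(n_bins)) {
    b <- add_months(birth_date, bin_months * k)
    acc <- acc + as.integer(!is.na(date) & date >= b)
  }
  out <- ifelse(acc >= n_bins | is.na(date) | is.na(birth_date), NA_integer_, acc)
  as.integer(out)
}

#' Infant-anchored six-month windows
#'
#' Calendar windows for one infant, anchored at its birth date and advancing
#' in six-month steps; window `k` spans ages \[6k, 6(k+1)) months.  Window
#' bounds are inclusive dates (`end` is the day before the next window
#' starts).
#'
#' @param birth_date infant birth date (scalar `Date`).
#' @param bins integer bin indices, default `0:6`.
#' @param bin_months bin width in calendar months.
#' @return a tibble with columns `bin`, `start`, `end`.
#' @export
infant_windows <- function(birth_date, bins = 0:6, bin_months = 6L) {
  birth_date <- as.Date(birth_date)
  stopifnot(length(birth_date) == 1L)
  tibble(
    bin = as.integer(bins),
    start = add_months(birth_date, bin_months * as.integer(bins)),
    end = add_months(birth_date, bin_months * (as.integer(bins) + 1L)) - 1L
  )
}

# add_months evaluated once per unique input (month rollback is costly on
# long repetitive vectors)
add_months_u <- function(x, n) {
  ux <- unique(x)
  add_months(ux, n)[match(x, ux)]
}

# default adulthood: 12 years after birth
default_adult_from <- function(birth_date) add_months(birth_date, 144L)

# adult males of the roster alive (and adult) on a given scalar date
adult_males_on <- function(roster, date) {
  date <- as.Date(date)
  roster |>
    filter(
      sex == "M",
      !is.na(adult_from), adult_from <= date,
      birth_date <= date,
      is.na(death_date) | death_date >= date
    )
}
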