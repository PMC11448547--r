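# Data model and I/O for verified supercentenarian death records observed
# through country-specific inclusion windows.

#' Country-to-region lookup for the 13 IDL countries
#'
#' Four-region partition used for region-stratified model fits and tests:
#' North America (Canada, United States), Northern Europe (Belgium, Denmark,
#' England and Wales, Finland, Germany, Norway, Sweden), Southern Europe
#' (Austria, France, Spain), and Japan.
#'
#' @return Named character vector mapping country code to region label.
#' @export
#' @examples
#' idl_regions()[["JP"]]
idl_regions <- function() {
  c(CA = "North America", US = "North America",
    BE = "Northern Europe", DK = "Northern Europe", EW = "Northern Europe",
    FI = "Northern Europe", DE = "Northern Europe", NO = "Northern Europe",
    SE = "Northern Europe",
    AT = "Southern Europe", FR = "Southern Europe", ES = "Southern Europe",
    JP = "Japan")
}

is_leap_year <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Convert a calendar date to a decimal year
#'
#' The fractional part is days elapsed since January 1 divided by the length
#' of the year (365 or 366).
#'
#' @param date a `Date` or anything `as.Date()` accepts.
#' @return Numeric decimal year.
#' @export
#' @examples
#' decimal_year("2001-07-02")
decimal_year <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  start <- as.Date(sprintf("%04d-01-01", y))
  y + as.numeric(date - start) / ifelse(is_leap_year(y), 366, 365)
}

#' Convert a decimal year to the nearest calendar date
#'
#' Inverse of [decimal_year()] up to day resolution.
#'
#' @param z numeric decimal year.
#' @return A `Date`.
#' @export
decimal_to_date <- function(z) {
  y <- floor(z)
  start <- as.Date(sprintf("%04d-01-01", y))
  start + round((z - y) * ifelse(is_leap_year(y), 366, 365))
}

#' Impute a decimal death time from a death year known only to the year
#'
#' US records in the IDL carry no day or month of death; the convention used
#' in the literature records them as July 1. The conventions are bit-stable:
#' `july1` gives `year + 0.5`, `jan1` gives `year`, `dec31` gives
#' `year + 364/365` regardless of leap years.
#'
#' @param year integer 4-digit calendar year(s).
#' @param convention one of `"july1"` (default), `"jan1"`, `"dec31"`.
#' @return Numeric decimal year(s).
#' @export
#' @examples
#' impute_death_time(2005, "july1")  # 2005.5
impute_death_time <- function(year, convention = c("july1", "jan1", "dec31")) {
  convention <- match.arg(convention)
  year <- as.numeric(year)
  if (any(!is.finite(year) | year < 1000 | year > 9999 | year != floor(year)))
    stop("'year' must be a 4-digit calendar year")
  year + switch(convention, july1 = 0.5, jan1 = 0, dec31 = 364 / 365)
}

# calendar date a year-only death is imputed to, matching the convention label
impute_death_date <- function(year, convention) {
  as.Date(sprintf("%04d-%s", year,
                  switch(convention, july1 = "07-01", jan1 = "01-01",
                         dec31 = "12-31")))
}

#' Classify a record's truncation case
#'
#' A record is case `"C1"` when the person attained age 110 at or before the
#' opening of the country's observation window (`t <= b`): the observable
#' excess lifetime is restricted on both sides. Otherwise it is case `"C2"`
#' (attained 110 inside the window; restricted on the right only). The
#' boundary `t == b` is C1.
#'
#' @param record a list or one-or-more-row data frame with element/column `t`
#'   (decimal year of attaining age 110).
#' @param window a list or one-row data frame with element `b` (window start,
#'   decimal year).
#' @return Character vector of `"C1"`/`"C2"`.
#' @export
#' @examples
#' classify_case(list(t = 1995), list(b = 2000, e = 2010))
classify_case <- function(record, window) {
  t <- if (is.list(record)) record$t else record
  b <- if (is.list(window)) window$b else window
  ifelse(t <= b, "C1", "C2")
}

#' Construct a supercentenarian dataset
#'
#' Core constructor validating records against their country observation
#' windows. Admission requires every record's country to have a window, a
#' non-negative excess age, and a death time inside the window `[b, e]`.
#' Violations are hard errors (the database guarantees inclusion, so a
#' violation means corrupted input), never silent drops.
#'
#' @param records data frame with columns `country`, `x` (excess age beyond
#'   110, years) and at least one of `t` (decimal year of reaching 110) or
#'   `death_time` (decimal year of death); optional `id`, `sex` (one of
#'   `"F"`, `"M"`, `"unknown"`), `validated`, `birth_date`, `death_date`,
#'   `death_year_only`.
#' @param windows data frame with columns `country`, `b`, `e` (decimal
#'   years); `e` may be `Inf` or `NA` for an unbounded window end.
#' @return An object of class `mrad_data`: a list with elements `records`
#'   (data frame, including the truncation `case`), `windows`, and `n`.
#' @seealso [read_records()], [fit_mle()], [simulate_dataset()]
#' @export
mrad_data <- function(records, windows) {
  records <- as.data.frame(records)
  windows <- as.data.frame(windows)
  stopifnot(all(c("country", "b", "e") %in% names(windows)),
            all(c("country", "x") %in% names(records)))
  windows$country <- as.character(windows$country)
  windows$e[is.na(windows$e)] <- Inf
  if (anyDuplicated(windows$country))
    stop("duplicated country in windows table")
  if (any(windows$b >= windows$e))
    stop("window start must be strictly before window end: ",
         paste(windows$country[windows$b >= windows$e], collapse = ", "))

  n <- nrow(records)
  records$country <- as.character(records$country)
  if (is.null(records$id)) records$id <- if (n) as.character(seq_len(n)) else character(0)
  if (is.null(records$sex)) records$sex <- rep("unknown", n)
  records$sex <- as.character(records$sex)
  bad_sex <- !records$sex %in% c("F", "M", "unknown")
  if (any(bad_sex)) stop("invalid sex value(s): ",
                         paste(unique(records$sex[bad_sex]), collapse = ", "))
  if (is.null(records$validated)) records$validated <- rep(TRUE, n)

  if (is.null(records$death_time) && is.null(records$t))
    stop("records need 't' or 'death_time'")
  if (is.null(records$death_time)) records$death_time <- records$t + records$x
  if (is.null(records$t)) records$t <- records$death_time - records$x

  if (any(records$x < 0))
    stop("negative excess age for record(s): ",
         paste(records$id[records$x < 0], collapse = ", "))
  miss <- setdiff(records$country, windows$country)
  if (length(miss))
    stop("no observation window for country: ", paste(miss, collapse = ", "))

  idx <- match(records$country, windows$country)
  b <- windows$b[idx]; e <- windows$e[idx]
  out <- records$death_time < b - 1e-9 | records$death_time > e + 1e-9
  if (any(out))
    stop("death time outside the country observation window for record(s): ",
         paste(records$id[out], collapse = ", "))
  records$case <- ifelse(records$t <= b, "C1", "C2")

  keep <- c("id", "country", "sex", "t", "death_time", "x", "validated",
            "case",
            intersect(c("birth_date", "death_date", "death_year_only"),
                      names(records)))
  structure(list(records = records[, keep, drop = FALSE],
                 windows = windows[, c("country", "b", "e")],
                 n = n),
            class = "mrad_data")
}

#' Read supercentenarian death records and observation windows from CSV
#'
#' Records CSV columns: `id,country,sex,birth_date,death_date,
#' death_year_only` (ISO dates; a non-empty `death_year_only` triggers
#' imputation of the death date at the chosen convention). Windows CSV
#' columns: `country,window_start,window_end` (decimal years; empty end =
#' unbounded).
#'
#' Decimal-year fields are computed from calendar dates: the excess age is
#' `x = (death - birth in days)/365.2425 - 110` and the age-110 attainment
#' time is `t = death_time - x`, with `death_time` the decimal year of the
#' death date.
#'
#' @param records_source,windows_source file path, connection, or literal CSV
#'   text.
#' @param convention death-date imputation convention for year-only records,
#'   see [impute_death_time()].
#' @return An [mrad_data] object.
#' @export
read_records <- function(records_source, windows_source,
                         convention = c("july1", "jan1", "dec31")) {
  convention <- match.arg(convention)
  rec <- read_csv_source(records_source)
  win <- read_csv_source(windows_source)
  need <- c("id", "country", "sex", "birth_date", "death_date",
            "death_year_only")
  if (!all(need %in% names(rec)))
    stop("records CSV must have columns: ", paste(need, collapse = ", "))
  if (!all(c("country", "window_start", "window_end") %in% names(win)))
    stop("windows CSV must have columns: country, window_start, window_end")

  yr_only <- !is.na(rec$death_year_only) & nzchar(trimws(rec$death_year_only))
  ddate <- as.Date(rep(NA, nrow(rec)))
  ddate[!yr_only] <- as.Date(rec$death_date[!yr_only])
  if (any(yr_only))
    ddate[yr_only] <- impute_death_date(as.integer(rec$death_year_only[yr_only]),
                                        convention)
  bdate <- as.Date(rec$birth_date)
  if (anyNA(ddate) || anyNA(bdate))
    stop("unparseable birth or death date for record(s): ",
         paste(rec$id[is.na(ddate) | is.na(bdate)], collapse = ", "))

  x <- as.numeric(ddate - bdate) / 365.2425 - 110
  death_time <- decimal_year(ddate)
  records <- data.frame(id = as.character(rec$id), country = rec$country,
                        sex = rec$sex, x = x, death_time = death_time,
                        birth_date = format(bdate),
                        death_date = ifelse(yr_only, "", format(ddate)),
                        death_year_only = ifelse(yr_only,
                                                 trimws(rec$death_year_only), ""),
                        stringsAsFactors = FALSE)
  windows <- data.frame(country = win$country,
                        b = as.numeric(win$window_start),
                        e = suppressWarnings(as.numeric(win$window_end)))
  mrad_data(records, windows)
}

read_csv_source <- function(src) {
  if (is.character(src) && length(src) == 1L && !file.exists(src) &&
      grepl("[,\n]", src))
    src <- textConnection(src)
  utils::read.csv(src, stringsAsFactors = FALSE, colClasses = "character",
                  strip.white = TRUE)
}

#' Write a dataset back to the records/windows CSV dialect
#'
#' Inverse of [read_records()]. Datasets read from CSV keep their original
#' date strings and round-trip bit-exactly. For simulated datasets without
#' calendar dates, dates are synthesized from the decimal-year fields at day
#' resolution (a quantization of less than 0.003 years on re-reading).
#'
#' @param data an [mrad_data] object.
#' @param records_path,windows_path output file paths.
#' @return Invisibly, `data`.
#' @export
write_records <- function(data, records_path, windows_path) {
  stopifnot(inherits(data, "mrad_data"))
  r <- data$records
  if (is.null(r$birth_date)) {
    ddate <- decimal_to_date(r$death_time)
    bdate <- ddate - round((110 + r$x) * 365.2425)
    r$birth_date <- format(bdate)
    r$death_date <- format(ddate)
    r$death_year_only <- rep("", nrow(r))
  }
  out <- data.frame(id = r$id, country = r$country, sex = r$sex,
                    birth_date = r$birth_date, death_date = r$death_date,
                    death_year_only = r$death_year_only)
  utils::write.csv(out, records_path, row.names = FALSE, quote = FALSE)
  w <- data$windows
  wout <- data.frame(country = w$country, window_start = w$b,
                     window_end = ifelse(is.finite(w$e), format(w$e), ""))
  utils::write.csv(wout, windows_path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' Raw empirical one-year survival probability at a given age
#'
#' The proportion of records that survived at least one more year among those
#' that attained the given age: `#{x >= age - 109} / #{x >= age - 110}`. This
#' is the raw proportion with no truncation adjustment, so it is a
#' descriptive diagnostic (the flat-mortality check) rather than an unbiased
#' estimate.
#'
#' @param data an [mrad_data] object.
#' @param age integer age of at least 110.
#' @return Proportion in `[0, 1]`.
#' @export
empirical_one_year_survival <- function(data, age) {
  stopifnot(inherits(data, "mrad_data"), age >= 110, age == floor(age))
  x <- data$records$x
  den <- sum(x >= age - 110)
  if (den == 0)
    stop(structure(class = c("mrad_undefined_value", "error", "condition"),
                   list(message = sprintf(
                     "no records attained age %d: survival undefined", age),
                     call = sys.call())))
  sum(x >= age - 109) / den
}

#' Record counts by country and by sex
#'
#' @param data an [mrad_data] object.
#' @return List with data frames `country` and `sex`, each ordered by
#'   descending count then code; counts sum to `n`.
#' @export
summary_counts <- function(data) {
  stopifnot(inherits(data, "mrad_data"))
  count_by <- function(v, levels = NULL) {
    tab <- table(if (is.null(levels)) v else factor(v, levels = levels))
    if (length(tab) == 0)
      return(data.frame(code = character(0), count = integer(0)))
    df <- data.frame(code = names(tab), count = as.integer(tab))
    df[order(-df$count, df$code), , drop = FALSE]
  }
  ctry <- count_by(data$records$country)
  if (data$n == 0) ctry <- data.frame(code = character(0), count = integer(0))
  list(country = ctry,
       sex = count_by(data$records$sex, c("F", "M", "unknown")))
}

#' @export
print.mrad_data <- function(x, ...) {
  cat(sprintf("Supercentenarian dataset: %d records, %d countries\n",
              x$n, nrow(x$windows)))
  tab <- table(factor(x$records$case, levels = c("C1", "C2")))
  cat(sprintf("Truncation cases: C1 = %d, C2 = %d\n", tab["C1"], tab["C2"]))
  invisible(x)
}

#' @export
summary.mrad_data <- function(object, ...) {
  cnt <- summary_counts(object)
  s <- list(n = object$n, counts = cnt,
            case = table(factor(object$records$case, c("C1", "C2"))),
            excess_age = if (object$n) summary(object$records$x) else NULL,
            windows = object$windows)
  class(s) <- "summary.mrad_data"
  s
}

#' @export
print.summary.mrad_data <- function(x, ...) {
  cat(sprintf("n = %d records (C1 = %d, C2 = %d)\n",
              x$n, x$case["C1"], x$case["C2"]))
  cat("\nBy country:\n"); print(x$counts$country, row.names = FALSE)
  cat("\nBy sex:\n"); print(x$counts$sex, row.names = FALSE)
  if (!is.null(x$excess_age)) {
    cat("\nExcess age beyond 110 (years):\n"); print(x$excess_age)
  }
  invisible(x)
}
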