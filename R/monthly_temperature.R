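#' Monthly mean temperature record
#'
#' A (year, month)-indexed record of monthly mean temperatures in degrees C,
#' the raw material for the seasonal and annual response series.
#'
#' @param year,month,temp equal-length vectors; `month` in 1..12.
#' @return an object of class `monthly_temperature` (a data frame with
#'   columns `year`, `month`, `temp`).
#' @export
monthly_temperature <- function(year, month, temp) {
  year <- as.integer(year)
  month <- as.integer(month)
  temp <- as.double(temp)
  stopifnot(length(year) == length(month), length(month) == length(temp))
  keep <- !is.na(temp)
  year <- year[keep]; month <- month[keep]; temp <- temp[keep]
  if (any(month < 1L | month > 12L))
    stop("month out of range 1..12", call. = FALSE)
  key <- year * 12L + month
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate (year, month) entry: ", year[d], "-", month[d], call. = FALSE)
  }
  o <- order(key)
  structure(data.frame(year = year[o], month = month[o], temp = temp[o]),
            class = c("monthly_temperature", "data.frame"))
}

#' @export
print.monthly_temperature <- function(x, ...) {
  cat(sprintf("<monthly_temperature: %d values, %d-%d>\n",
              nrow(x), min(x$year), max(x$year)))
  invisible(x)
}

#' Read monthly temperatures from delimited text
#'
#' Two layouts are accepted: long format with rows `year,month,value`, or
#' wide format with rows `year,Jan,...,Dec` (13 columns).  `#`-comments,
#' optional header and `NA` cells are allowed.
#'
#' @param path file path.
#' @return a [monthly_temperature].
#' @export
read_monthly_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, .split_fields)
  rows <- rows[vapply(rows, length, 1L) > 0L]
  if (length(rows) == 0L) stop("no usable rows in '", path, "'", call. = FALSE)
  # drop one header line if the first field is non-numeric
  if (is.na(suppressWarnings(as.numeric(rows[[1]][1])))) rows <- rows[-1]
  widths <- vapply(rows, length, 1L)
  num <- function(x) suppressWarnings(as.numeric(ifelse(toupper(x) == "NA", NA, x)))
  if (all(widths == 13L)) {
    year <- rep(vapply(rows, function(r) as.integer(num(r[1])), 1L), each = 12L)
    month <- rep.int(1:12, length(rows))
    temp <- unlist(lapply(rows, function(r) num(r[2:13])))
  } else if (all(widths == 3L)) {
    year <- vapply(rows, function(r) as.integer(num(r[1])), 1L)
    month <- vapply(rows, function(r) as.integer(num(r[2])), 1L)
    temp <- vapply(rows, function(r) num(r[3]), 1)
  } else {
    stop("'", path, "' is neither 3-column long nor 13-column wide format",
         call. = FALSE)
  }
  monthly_temperature(year, month, temp)
}

#' Write monthly temperatures in long CSV format
#'
#' @param mt a [monthly_temperature].
#' @param path output file path.
#' @export
write_monthly_csv <- function(mt, path) {
  stopifnot(inherits(mt, "monthly_temperature"))
  writeLines(c("year,month,temp",
               sprintf("%d,%d,%.10g", mt$year, mt$month, mt$temp)), path)
}

#' Season definitions
#'
#' Meteorological seasons: spring = MAM, summer = JJA, autumn = SON,
#' winter = DJF where winter of year t spans December of t-1 plus
#' January-February of t, and annual = the 12 calendar months of t.
#'
#' @param season one of `"spring"`, `"summer"`, `"autumn"`, `"winter"`,
#'   `"annual"`.
#' @return a data frame with columns `offset` (year offset, 0 or -1) and
#'   `month`.
#' @export
season_months <- function(season) {
  season <- match.arg(season, c("spring", "summer", "autumn", "winter", "annual"))
  switch(season,
    spring = data.frame(offset = 0L, month = 3:5),
    summer = data.frame(offset = 0L, month = 6:8),
    autumn = data.frame(offset = 0L, month = 9:11),
    winter = data.frame(offset = c(-1L, 0L, 0L), month = c(12L, 1L, 2L)),
    annual = data.frame(offset = 0L, month = 1:12))
}

#' All season labels
#' @export
seasons <- function() c("spring", "summer", "autumn", "winter", "annual")

#' Seasonal or annual mean temperature series
#'
#' Computes, for every year in which all required months are present, the
#' arithmetic mean temperature of the season's months.  Winter of year t uses
#' December of t-1 with January and February of t, so the first winter of a
#' record (missing the preceding December) is absent.  Years with any
#' required month missing are absent from the result.
#'
#' @param mt a [monthly_temperature].
#' @param season a season label, see [season_months()].
#' @return an [annual_series] in degrees C, named `<season>_temperature`.
#' @export
seasonal_mean <- function(mt, season) {
  stopifnot(inherits(mt, "monthly_temperature"))
  sm <- season_months(season)
  lookup <- mt$temp
  names(lookup) <- paste(mt$year, mt$month)
  years <- sort(unique(mt$year + max(0L, -min(sm$offset))))
  years <- seq.int(min(mt$year), max(mt$year) + max(0L, -min(sm$offset)))
  vals <- vapply(years, function(y) {
    v <- lookup[paste(y + sm$offset, sm$month)]
    if (anyNA(v)) NA_real_ else mean(v)
  }, 1)
  keep <- !is.na(vals)
  if (!any(keep))
    stop("no year has all months required for season '", season, "'",
         call. = FALSE)
  annual_series(years[keep], vals[keep],
                name = paste0(season, "_temperature"))
}
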