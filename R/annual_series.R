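#' Annual indicator series
#'
#' The universal container for a year-indexed indicator or response: phenology
#' dates (day of year), ice melt/freeze dates, ice extent (km^2), ring-width
#' indices, densities, delta-13-C values or temperatures (degrees C).  Missing
#' years are simply absent -- no sentinel values are stored.
#'
#' @param years integer years; must be unique.  Entries whose value is `NA`
#'   are dropped.
#' @param values numeric values, one per year.
#' @param name a short label for the series.
#' @return an object of class `annual_series`: a list with elements `name`,
#'   `years` (strictly increasing integers) and `values`.
#' @examples
#' s <- annual_series(c(2000, 2001, 2003), c(152, 148, 150), name = "budburst")
#' series_values(s, 1999:2003)
#' @export
annual_series <- function(years, values, name = "series") {
  stopifnot(length(years) == length(values), is.character(name), length(name) == 1L)
  years <- as.integer(years)
  values <- as.double(values)
  keep <- !is.na(values)
  years <- years[keep]
  values <- values[keep]
  if (length(years) == 0L)
    stop("annual series '", name, "' has no non-missing values", call. = FALSE)
  if (anyNA(years)) stop("NA year in series '", name, "'", call. = FALSE)
  if (anyDuplicated(years))
    stop("duplicate year ", years[duplicated(years)][1L], " in series '", name, "'",
         call. = FALSE)
  o <- order(years)
  structure(list(name = name, years = years[o], values = values[o]),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series '%s': %d years, %d-%d>\n",
              x$name, length(x$years), min(x$years), max(x$years)))
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = x$years, value = x$values)
}

#' @export
length.annual_series <- function(x) length(x$years)

#' Look up series values for given years
#'
#' @param s an [annual_series].
#' @param years integer years.
#' @return numeric vector, `NA` where the year is absent from the series.
#' @export
series_values <- function(s, years) {
  stopifnot(inherits(s, "annual_series"))
  s$values[match(as.integer(years), s$years)]
}

#' Restrict a series to a window of years
#'
#' @param s an [annual_series].
#' @param from,to first and last year kept (inclusive); `NULL` leaves that
#'   end open.
#' @param drop integer years to remove (to mimic observation gaps).
#' @export
series_window <- function(s, from = NULL, to = NULL, drop = NULL) {
  stopifnot(inherits(s, "annual_series"))
  keep <- rep(TRUE, length(s$years))
  if (!is.null(from)) keep <- keep & s$years >= from
  if (!is.null(to)) keep <- keep & s$years <= to
  if (!is.null(drop)) keep <- keep & !(s$years %in% as.integer(drop))
  annual_series(s$years[keep], s$values[keep], name = s$name)
}

# ---- file I/O --------------------------------------------------------------

# Split a data line on commas or whitespace; '#' starts a comment.
.split_fields <- function(line) {
  line <- sub("#.*$", "", line)
  line <- trimws(line)
  if (!nzchar(line)) return(character(0))
  strsplit(line, "[,;\t ]+")[[1]]
}

#' Read an annual series from a two-column delimited text file
#'
#' Accepts `year,value` rows, comma- or whitespace-delimited; an optional
#' header line; `#`-comments; blank or `NA` value cells (those years are
#' treated as missing and dropped).
#'
#' @param path file path.
#' @param name label for the resulting series; defaults to the file name.
#' @return an [annual_series].
#' @export
read_annual_csv <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  years <- integer(0)
  values <- double(0)
  for (i in seq_along(lines)) {
    f <- .split_fields(lines[i])
    if (length(f) == 0L) next
    yr <- suppressWarnings(as.numeric(f[1]))
    if (is.na(yr)) {
      # a non-numeric first field is only tolerated as a single header line
      if (length(years) == 0L && !grepl("^[0-9.+-]", f[1])) next
      stop("unparsable row at line ", i, " of '", path, "'", call. = FALSE)
    }
    if (length(f) < 2L)
      stop("unparsable row at line ", i, " of '", path, "' (need year,value)",
           call. = FALSE)
    if (yr %in% years)
      stop("duplicate year ", as.integer(yr), " in '", path, "'", call. = FALSE)
    val <- if (toupper(f[2]) %in% c("NA", "NAN", "")) NA_real_
           else suppressWarnings(as.numeric(f[2]))
    if (!toupper(f[2]) %in% c("NA", "NAN", "") && is.na(val))
      stop("unparsable value at line ", i, " of '", path, "'", call. = FALSE)
    years <- c(years, as.integer(yr))
    values <- c(values, val)
  }
  if (all(is.na(values)))
    stop("no usable rows in '", path, "'", call. = FALSE)
  annual_series(years, values, name = name)
}

#' Write an annual series as two-column CSV
#'
#' @param s an [annual_series].
#' @param path output file path.
#' @export
write_annual_csv <- function(s, path) {
  stopifnot(inherits(s, "annual_series"))
  writeLines(c("year,value", sprintf("%d,%.10g", s$years, s$values)), path)
}
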