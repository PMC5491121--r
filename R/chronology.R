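#' Tree-ring chronology building
#'
#' Standard dendroclimatological chronology construction: each measurement
#' series is detrended with a smoothing spline whose amplitude response is 50%
#' at a chosen wavelength, indices are formed by division, optionally
#' prewhitened with an AR(1) model, and the per-year site index is the Tukey
#' biweight robust mean across trees.
#'
#' @name chronology
NULL

# Second-difference penalized smoother (the discrete form of a cubic
# smoothing spline).  The penalty lambda is set analytically so that the
# filter's amplitude frequency response equals `f` at wavelength
# `cutoff_years`: H(w) = 1 / (1 + lambda * (2 - 2 cos w)^2), w = 2*pi/cutoff.
smoothing_spline_fit <- function(y, cutoff_years, f = 0.5) {
  n <- length(y)
  w <- 2 * pi / cutoff_years
  lambda <- (1 / f - 1) / (2 - 2 * cos(w))^2
  D <- diff(diag(n), differences = 2L)
  s <- solve(diag(n) + lambda * crossprod(D), y)
  as.double(s)
}

#' Detrend a ring series by a smoothing spline, indices by division
#'
#' Fits a smoothing spline with a 50% frequency cut-off at `cutoff_years`
#' (default 60) to the raw measurements and returns the dimensionless
#' indices `value / fit`.  Variance at wavelengths much longer than the
#' cut-off (age and size trends) is absorbed into the fitted curve; the
#' interannual climate signal passes through.
#'
#' @param rs a [ring_series] with >= 10 rings.
#' @param cutoff_years wavelength (years) at which the spline's amplitude
#'   response is 0.5.
#' @return an [annual_series] of indices with mean approximately 1.
#' @export
spline_detrend <- function(rs, cutoff_years = 60L) {
  stopifnot(inherits(rs, "ring_series"))
  n <- length(rs$values)
  if (n < 10L)
    stop("series '", rs$id, "' too short to detrend (", n, " < 10 rings)",
         call. = FALSE)
  fit <- smoothing_spline_fit(rs$values, cutoff_years)
  if (any(fit <= 0))
    stop("degenerate detrend for series '", rs$id,
         "': fitted growth curve is not positive", call. = FALSE)
  annual_series(ring_years(rs), rs$values / fit, name = rs$id)
}

#' Prewhiten an index series with an AR(1) model
#'
#' Fits a first-order autoregression by ordinary least squares on the
#' (x_t, x_{t-1}) pairs and returns the residuals plus the series mean, so
#' the index level (approximately 1) is retained while lag-1 persistence is
#' removed.  The first year of the input has no predecessor and is absent
#' from the output.
#'
#' @param idx an [annual_series] of >= 10 contiguous values.
#' @return an [annual_series] of prewhitened indices.
#' @export
prewhiten_ar1 <- function(idx) {
  stopifnot(inherits(idx, "annual_series"))
  x <- idx$values
  n <- length(x)
  if (n < 10L) stop("series too short to prewhiten (", n, " < 10)", call. = FALSE)
  if (any(diff(idx$years) != 1L))
    stop("prewhitening needs contiguous years in '", idx$name, "'", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in '", idx$name, "': cannot prewhiten", call. = FALSE)
  x0 <- x[-n] - mean(x[-n])
  x1 <- x[-1] - mean(x[-1])
  phi <- sum(x0 * x1) / sum(x0 * x0)
  res <- x[-1] - mean(x[-1]) - phi * x0
  annual_series(idx$years[-1], res + mean(x), name = idx$name)
}

#' Tukey's biweight robust mean
#'
#' Iteratively reweighted biweight location estimate: starting from the
#' median, weights `(1 - u^2)^2` for `|u| < 1` (0 otherwise) with
#' `u = (x - m) / (c * MAD)`, iterated until the location moves by less than
#' 1e-8.  If the MAD is zero the median is returned.
#'
#' @param values numeric vector, length >= 1.
#' @param c tuning constant (9 is the conventional dendrochronology choice:
#'   observations further than 9 median absolute deviations get zero weight).
#' @return the robust location (a scalar).
#' @export
biweight_mean <- function(values, c = 9) {
  x <- as.double(values)
  if (length(x) == 0L || anyNA(x)) stop("biweight_mean needs >= 1 non-NA value",
                                        call. = FALSE)
  m <- stats::median(x)
  for (it in 1:2000) {
    s <- stats::median(abs(x - m))
    if (s == 0) return(m)
    u <- (x - m) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < 1e-11) return(m_new)
    m <- m_new
  }
  m
}

#' Site chronology with per-year sample depth
#'
#' @param index an [annual_series] of dimensionless site indices.
#' @param sample_depth integer vector, one count per year of `index`.
#' @return an object of class `chronology`.
#' @export
chronology <- function(index, sample_depth) {
  stopifnot(inherits(index, "annual_series"),
            length(sample_depth) == length(index$years),
            all(sample_depth >= 1L))
  structure(list(index = index,
                 sample_depth = stats::setNames(as.integer(sample_depth),
                                                index$years)),
            class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology '%s': %d years, depth %d-%d>\n",
              x$index$name, length(x$index$years),
              min(x$sample_depth), max(x$sample_depth)))
  invisible(x)
}

#' Build a chronology from raw measurement series
#'
#' Detrends every series ([spline_detrend]), optionally prewhitens
#' ([prewhiten_ar1]; conventional for ring widths, usually skipped for
#' density), and combines them year by year with the biweight robust mean.
#' Years covered by fewer than `min_depth` series are absent.
#'
#' @param series list of [ring_series].
#' @param cutoff spline 50% frequency cut-off in years.
#' @param min_depth minimum number of contributing series per retained year.
#' @param prewhiten logical.
#' @param name chronology label.
#' @return a [chronology].
#' @export
build_chronology <- function(series, cutoff = 60L, min_depth = 5L,
                             prewhiten = TRUE, name = "chronology") {
  if (inherits(series, "ring_series")) series <- list(series)
  stopifnot(length(series) >= 1L)
  idx <- lapply(series, function(rs) {
    out <- tryCatch({
      d <- spline_detrend(rs, cutoff_years = cutoff)
      if (prewhiten) prewhiten_ar1(d) else d
    }, error = function(e)
      stop("series '", rs$id, "': ", conditionMessage(e), call. = FALSE))
    out
  })
  years <- sort(unique(unlist(lapply(idx, function(s) s$years))))
  vals_by_year <- lapply(years, function(y) {
    v <- vapply(idx, function(s) series_values(s, y), 1)
    v[!is.na(v)]
  })
  depth <- vapply(vals_by_year, length, 1L)
  keep <- depth >= min_depth
  if (!any(keep))
    stop("no year reaches the minimum sample depth of ", min_depth, call. = FALSE)
  vals <- vapply(vals_by_year[keep], biweight_mean, 1)
  chronology(annual_series(years[keep], vals, name = name), depth[keep])
}

#' Split ring series at a latitude boundary
#'
#' Northern boreal sites typically carry a stronger temperature signal than
#' southern ones; chronologies are built per region.  Series at exactly the
#' boundary go north.
#'
#' @param series list of [ring_series], each with a latitude.
#' @param boundary decimal degrees north.
#' @return a list with elements `south` (lat < boundary) and `north`
#'   (lat >= boundary).
#' @export
split_by_latitude <- function(series, boundary = 66.5) {
  if (inherits(series, "ring_series")) series <- list(series)
  lat <- vapply(series, function(rs) rs$latitude, 1)
  if (anyNA(lat)) {
    bad <- vapply(series, function(rs) rs$id, "")[is.na(lat)]
    stop("missing latitude for series: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(south = series[lat < boundary], north = series[lat >= boundary])
}

#' Export a chronology as annual CSV with a sample-depth column
#'
#' @param ch a [chronology].
#' @param path output file path.
#' @export
write_chronology_csv <- function(ch, path) {
  stopifnot(inherits(ch, "chronology"))
  writeLines(c("year,index,sample_depth",
               sprintf("%d,%.10g,%d", ch$index$years, ch$index$values,
                       ch$sample_depth)), path)
}
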