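#' Design matrix aligning indicator series with a temperature response
#'
#' `align()` assembles the year-by-indicator design matrix behind every model
#' in the package.  Rows are the years in which the response exists; cells
#' where an indicator has no observation are `NA` (flagged, never imputed).
#' Model fitting downstream is complete-case per fitted model.
#'
#' @param indicators a list of [annual_series] (or a single one).
#' @param response an [annual_series], typically from [seasonal_mean()].
#' @return an object of class `indicator_matrix`: list with `years`, `columns`
#'   (data frame of `name`, `lag`), `X` (matrix, `NA` = missing), `y`
#'   (response values) and `series` (the source series, kept so that lagged
#'   columns can be filled from years outside the response window).
#' @export
align <- function(indicators, response) {
  if (inherits(indicators, "annual_series")) indicators <- list(indicators)
  stopifnot(length(indicators) >= 1L,
            all(vapply(indicators, inherits, TRUE, "annual_series")),
            inherits(response, "annual_series"))
  nm <- unname(vapply(indicators, function(s) s$name, ""))
  if (anyDuplicated(nm))
    stop("duplicate indicator name: ", nm[duplicated(nm)][1L], call. = FALSE)
  years <- response$years
  X <- vapply(indicators, function(s) series_values(s, years),
              numeric(length(years)))
  X <- matrix(X, nrow = length(years), dimnames = list(years, nm))
  if (all(colSums(!is.na(X)) == 0L))
    stop("no indicator shares any year with the response", call. = FALSE)
  structure(list(years = years,
                 columns = data.frame(name = nm, lag = 0L),
                 X = X,
                 y = response$values,
                 response_name = response$name,
                 series = stats::setNames(indicators, nm)),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("<indicator_matrix: %d years x %d columns, response '%s', %d missing cells>\n",
              length(x$years), ncol(x$X), x$response_name, sum(is.na(x$X))))
  invisible(x)
}

# Column labels of an indicator matrix ("name" or "name_lag1").
column_labels <- function(m) {
  ifelse(m$columns$lag == 0L, m$columns$name,
         paste0(m$columns$name, "_lag", m$columns$lag))
}

#' Append lagged copies of indicator columns
#'
#' For annual-temperature models the indicators of the preceding year(s) can
#' carry additional signal (late-year events inform the early part of the
#' annual mean).  `add_lags()` appends, for each named indicator, columns
#' holding its value `lag` years earlier; values come from the original
#' series, so a lagged cell can be filled even when the lagged year itself is
#' not a response year.  Existing cells are never modified.
#'
#' @param m an [align()]ed `indicator_matrix`.
#' @param names indicator names to lag (must exist at lag 0).
#' @param max_lag largest lag, >= 1; columns for lags 1..`max_lag` are added.
#' @return the augmented `indicator_matrix`.
#' @export
add_lags <- function(m, names, max_lag = 1L) {
  stopifnot(inherits(m, "indicator_matrix"), max_lag >= 1L)
  unknown <- setdiff(names, m$columns$name[m$columns$lag == 0L])
  if (length(unknown))
    stop("unknown indicator column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names) {
    s <- m$series[[nm]]
    for (lag in seq_len(max_lag)) {
      if (any(m$columns$name == nm & m$columns$lag == lag)) next
      col <- series_values(s, m$years - lag)
      m$X <- cbind(m$X, col)
      m$columns <- rbind(m$columns, data.frame(name = nm, lag = as.integer(lag)))
    }
  }
  colnames(m$X) <- column_labels(m)
  m
}

# Rows of m usable for a model over column labels `vars`: complete in those
# columns (the response is complete by construction).
usable_rows <- function(m, vars) {
  idx <- match(vars, column_labels(m))
  if (anyNA(idx))
    stop("unknown model variable(s): ",
         paste(vars[is.na(idx)], collapse = ", "), call. = FALSE)
  which(stats::complete.cases(m$X[, idx, drop = FALSE]))
}
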