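#' A single tree-ring measurement series
#'
#' Raw per-tree ring measurements: widths in mm or densities in g/cm^3,
#' contiguous from the first year.
#'
#' @param id series identifier (<= 8 characters for RWL round-tripping).
#' @param first_year calendar year of the first ring.
#' @param values positive ring measurements, one per consecutive year.
#' @param latitude site latitude in decimal degrees (may be `NA`).
#' @param species species label.
#' @return an object of class `ring_series`.
#' @export
ring_series <- function(id, first_year, values, latitude = NA_real_,
                        species = NA_character_) {
  values <- as.double(values)
  if (length(values) == 0L) stop("empty ring series '", id, "'", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("non-positive or missing ring value in series '", id, "'", call. = FALSE)
  structure(list(id = as.character(id), first_year = as.integer(first_year),
                 values = values, latitude = as.double(latitude),
                 species = as.character(species)),
            class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series '%s': %d rings, %d-%d%s>\n", x$id,
              length(x$values), x$first_year, x$first_year + length(x$values) - 1L,
              if (is.na(x$latitude)) "" else sprintf(", lat %.1f", x$latitude)))
  invisible(x)
}

ring_years <- function(rs) seq.int(rs$first_year, length.out = length(rs$values))

#' Read a Tucson/RWL decadal tree-ring file
#'
#' The decadal layout used by the ITRDB: series id in columns 1-8, then the
#' decade's first year, then up to ten measurement fields per line.  The
#' series terminator also declares the measurement units: `999` for 0.01 mm,
#' `-9999` for 0.001 mm.  Values are returned converted to mm.
#'
#' @param path file path.
#' @return a list of [ring_series] (latitude/species are `NA`; RWL carries no
#'   site metadata).
#' @export
read_rwl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur_id <- NULL; cur_first <- NULL; cur_vals <- NULL; last_decade <- NULL
  flush_open <- function() {
    if (!is.null(cur_id))
      stop("series '", cur_id, "' has no terminator (999 or -9999)",
           call. = FALSE)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    id <- trimws(substr(ln, 1L, 8L))
    rest <- strsplit(trimws(substr(ln, 9L, nchar(ln))), "[ \t]+")[[1]]
    nums <- suppressWarnings(as.numeric(rest))
    if (anyNA(nums) || length(nums) < 2L)
      stop("unparsable RWL line for series '", id, "'", call. = FALSE)
    year <- as.integer(nums[1])
    vals <- nums[-1]
    if (is.null(cur_id)) {
      cur_id <- id; cur_first <- year; cur_vals <- double(0); last_decade <- year - 10L
    } else if (id != cur_id) {
      flush_open()
    }
    if (year <= last_decade)
      stop("non-monotone decade years in series '", cur_id, "'", call. = FALSE)
    last_decade <- year
    term <- which(vals == 999 | vals == -9999)
    if (length(term)) {
      t1 <- term[1L]
      scale <- if (vals[t1] == -9999) 1e-3 else 1e-2
      cur_vals <- c(cur_vals, vals[seq_len(t1 - 1L)])
      out[[length(out) + 1L]] <- ring_series(cur_id, cur_first, cur_vals * scale)
      cur_id <- NULL
    } else {
      cur_vals <- c(cur_vals, vals)
    }
  }
  flush_open()
  out
}

#' Write ring series in Tucson/RWL decadal format
#'
#' @param series a list of [ring_series] (values in mm).
#' @param path output file path.
#' @param precision `0.01` (terminator 999) or `0.001` (terminator -9999) mm.
#' @export
write_rwl <- function(series, path, precision = 0.01) {
  if (inherits(series, "ring_series")) series <- list(series)
  stopifnot(precision %in% c(0.01, 0.001))
  term <- if (precision == 0.01) 999L else -9999L
  lines <- character(0)
  for (rs in series) {
    yrs <- ring_years(rs)
    ints <- as.integer(round(rs$values / precision))
    fields <- c(sprintf("%6d", ints), sprintf("%6d", term))
    fyears <- c(yrs, max(yrs) + 1L)
    i <- 1L
    while (i <= length(fields)) {
      y <- fyears[i]
      n_in_line <- min(10L - (y %% 10L), length(fields) - i + 1L)
      lines <- c(lines, paste0(sprintf("%-8s", rs$id), sprintf("%4d", y),
                               paste(fields[i:(i + n_in_line - 1L)], collapse = "")))
      i <- i + n_in_line
    }
  }
  writeLines(lines, path)
}
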