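# Internal helpers: seed management and small numeric utilities.

#' Derive a reproducible sub-seed from a master seed
#'
#' Randomized operations in proxyrel never share one RNG stream: each unit of
#' work (a repeat, a fold, a model specification) gets its own seed derived
#' deterministically from the master seed and a label or index.  Adding a new
#' specification to a study therefore does not perturb the results of the
#' others.
#'
#' @param seed master seed (integer-valued scalar).
#' @param key an integer index or a character label identifying the unit of
#'   work.
#' @return an integer in `[1, 2^31 - 20]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  m <- 2147483629 # large prime < 2^31
  h <- as.double(seed) %% m
  if (is.character(key)) {
    for (b in utf8ToInt(key)) h <- (h * 69621 + b) %% m
  } else {
    h <- (h * 69621 + as.double(key) %% m) %% m
  }
  as.integer(h %% (m - 20)) + 1L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.  seed = NULL means: use the current stream as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Map a vector of years to positions in a reference year vector (NA if absent).
match_years <- function(years, ref_years) match(years, ref_years)

`%||%` <- function(a, b) if (is.null(a)) b else a
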