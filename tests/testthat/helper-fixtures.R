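# Shared fixtures built in code at test time.

# A small monthly climate for fast tests.
tiny_climate <- function(seed = 1, years = 1901:1960, ...) {
  gen_monthly_temperature(climate_config(years = years, seed = seed, ...))
}

# A constant monthly record: every month of every year = `value` degrees C.
constant_climate <- function(years = 2000:2009, value = -5) {
  grid <- expand.grid(month = 1:12, year = years)
  monthly_temperature(grid$year, grid$month, rep(value, nrow(grid)))
}

# Indicator matrix with p standardizable noise columns driven (or not) by a
# seasonal temperature; returns list(m, response).
noise_matrix <- function(n_years = 120, p = 12, seed = 1, season = "summer") {
  mt <- tiny_climate(seed = derive_seed(seed, "clim"),
                     years = seq(1901, length.out = n_years))
  resp <- seasonal_mean(mt, season)
  ind <- lapply(seq_len(p), function(j)
    annual_series(resp$years,
                  withr::with_seed(derive_seed(seed, j), stats::rnorm(n_years)),
                  name = paste0("noise", j)))
  list(m = align(ind, resp), response = resp, temperature = mt)
}

# An independent straight-from-the-definition Tukey biweight (reference
# implementation for cross-checking biweight_mean).
ref_biweight <- function(x, c = 9) {
  m <- median(x)
  for (i in 1:5000) {
    s <- median(abs(x - m))
    if (s == 0) return(m)
    u <- (x - m) / (c * s)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    m_new <- weighted.mean(x, w)
    if (abs(m_new - m) < 1e-12) return(m_new)
    m <- m_new
  }
  m
}

# Least-squares amplitude of a sinusoid of known wavelength in a series.
sinusoid_amplitude <- function(t, x, wavelength) {
  f <- lm(x ~ sin(2 * pi * t / wavelength) + cos(2 * pi * t / wavelength))
  sqrt(sum(coef(f)[2:3]^2))
}
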