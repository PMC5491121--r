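#' Synthetic climate and indicator generators
#'
#' Generators producing data with the statistical structure the analysis
#' assumes -- a linear seasonal-temperature signal plus (possibly serially
#' correlated) noise, multiplicative tree-ring structure, an energy-balance
#' ice-melt model -- with known ground truth, so the whole evaluation
#' pipeline can be validated against data whose reliability is known by
#' construction.
#'
#' @name synthetic
NULL

#' Configuration of the synthetic monthly climate
#'
#' A stylized boreal station: strongly negative winter and mild summer
#' monthly normals, interannual anomalies drawn per season and shared by
#' the months of that season, and an optional linear trend.
#'
#' @param years calendar years to generate (span >= 30 recommended for
#'   pipeline use).
#' @param climatology 12 monthly mean temperatures (degrees C, Jan..Dec).
#' @param anomaly_sd interannual anomaly standard deviation (degrees C):
#'   a scalar, or a length-4 vector for spring/summer/autumn/winter
#'   (winter anomalies are the largest at boreal stations).
#' @param trend linear trend in degrees C per century (default 0).
#' @param seed RNG seed.
#' @return an object of class `climate_config`.
#' @export
climate_config <- function(years = 1881:2020,
                           climatology = c(-8.5, -8.5, -4, 2.5, 9.5, 14.5,
                                           17, 15, 9.5, 4, -1.5, -6),
                           anomaly_sd = c(spring = 1.2, summer = 1.0,
                                          autumn = 1.2, winter = 2.2),
                           trend = 0, seed = NULL) {
  stopifnot(length(climatology) == 12L, all(anomaly_sd > 0),
            length(anomaly_sd) %in% c(1L, 4L))
  if (length(anomaly_sd) == 1L)
    anomaly_sd <- rep(anomaly_sd, 4L)
  names(anomaly_sd) <- c("spring", "summer", "autumn", "winter")
  structure(list(years = as.integer(years), climatology = climatology,
                 anomaly_sd = anomaly_sd, trend = trend, seed = seed),
            class = "climate_config")
}

# season index 1..4 (spring/summer/autumn/winter) of a calendar month
.month_season <- function(month) {
  c(4L, 4L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L)[month]
}

#' Generate a synthetic monthly temperature record
#'
#' Each month's value is the monthly normal plus the interannual anomaly of
#' its season (December belongs to the following year's winter) plus the
#' trend.  Months of one season in one year share one anomaly draw, so the
#' seasonal mean series has exactly the configured anomaly SD.
#'
#' @param cfg a [climate_config].
#' @return a [monthly_temperature].
#' @export
gen_monthly_temperature <- function(cfg) {
  stopifnot(inherits(cfg, "climate_config"))
  yrs <- cfg$years
  with_seed(cfg$seed, {
    # anomaly[y, s]: seasons indexed spring/summer/autumn/winter; winter of
    # year max+1 is needed for December of the final year
    anom_years <- c(yrs, max(yrs) + 1L)
    anom <- matrix(stats::rnorm(length(anom_years) * 4L), ncol = 4L,
                   dimnames = list(anom_years, NULL))
    anom <- sweep(anom, 2L, cfg$anomaly_sd, "*")
    grid <- expand.grid(month = 1:12, year = yrs)
    s <- .month_season(grid$month)
    anno_year <- grid$year + as.integer(grid$month == 12L)
    temp <- cfg$climatology[grid$month] +
      anom[cbind(match(anno_year, anom_years), s)] +
      cfg$trend * (grid$year - yrs[1]) / 100
    monthly_temperature(grid$year, grid$month, temp)
  })
}

#' Generate an indicator linearly driven by a seasonal temperature
#'
#' `value_t = intercept + slope * T_season(t) + e_t`, with AR(1) noise of
#' marginal standard deviation `noise_sd` and lag-1 correlation `phi`.
#' Exactly one of `slope`+`noise_sd` or `r2` must be given: under the `r2`
#' parameterization the noise SD is set so the population share of variance
#' contributed by the temperature term equals `r2` (using the realized
#' variance of the generated seasonal series).  Spring events (phenology,
#' ice melt) conventionally use a negative direction -- warm springs give
#' earlier dates; freeze dates use a positive one.
#'
#' @param mt a [monthly_temperature].
#' @param season driving season label.
#' @param slope units per degree C (signed), with `noise_sd`; or `NULL`.
#' @param noise_sd marginal noise SD in indicator units.
#' @param r2 target population R-squared in (0, 1]; alternative
#'   parameterization.
#' @param direction sign of the slope under the `r2` parameterization
#'   (-1 = warmer is earlier/less, +1 = warmer is later/more).
#' @param phi lag-1 serial correlation of the noise, in [0, 1).  Values
#'   around 0.4-0.5 mimic tree-ring isotope chronologies.
#' @param intercept indicator value at 0 degrees C.
#' @param seed RNG seed.
#' @param name series label.
#' @return an [annual_series]; attribute `truth` records the generating
#'   season, slope and R-squared.
#' @export
gen_linear_indicator <- function(mt, season, slope = NULL, noise_sd = NULL,
                                 r2 = NULL, direction = -1, phi = 0,
                                 intercept = 0, seed = NULL,
                                 name = "indicator") {
  stopifnot(phi >= 0, phi < 1)
  if (is.null(r2) == (is.null(slope) || is.null(noise_sd)))
    stop("give exactly one of {slope + noise_sd} or {r2}", call. = FALSE)
  Ts <- seasonal_mean(mt, season)
  n <- length(Ts$years)
  if (!is.null(r2)) {
    stopifnot(r2 > 0, r2 <= 1)
    slope <- direction * 3
    noise_sd <- abs(slope) * stats::sd(Ts$values) * sqrt((1 - r2) / r2)
  }
  e <- with_seed(seed, {
    innov <- stats::rnorm(n)
    e <- numeric(n)
    e[1] <- innov[1]
    for (t in seq_len(n)[-1]) e[t] <- phi * e[t - 1] + sqrt(1 - phi^2) * innov[t]
    e * noise_sd
  })
  vals <- intercept + slope * Ts$values + e
  out <- annual_series(Ts$years, vals, name = name)
  attr(out, "truth") <- list(season = season, slope = slope,
                             noise_sd = noise_sd,
                             r2 = if (!is.null(r2)) r2 else
                               (slope^2 * stats::var(Ts$values)) /
                               (slope^2 * stats::var(Ts$values) + noise_sd^2))
  out
}

#' Physical constants of the lake-ice energy balance
#'
#' @param latent_heat latent heat of fusion of ice, kJ/kg.
#' @param ice_density kg/m^3.
#' @param thickness ice-cover thickness, m.
#' @return an object of class `ice_constants`.
#' @export
ice_constants <- function(latent_heat = 333, ice_density = 917,
                          thickness = 0.5) {
  stopifnot(latent_heat > 0, ice_density > 0, thickness >= 0)
  structure(list(latent_heat = latent_heat, ice_density = ice_density,
                 thickness = thickness), class = "ice_constants")
}

#' Energy required to melt an ice cover, per square metre
#'
#' `latent_heat * ice_density * thickness`.  A 0.5 m cover of solid ice
#' needs about 1.5e5 kJ/m^2 -- the energy pool whose year-to-year
#' availability drives the variation in ice break-up dates.
#'
#' @param k an [ice_constants].
#' @return energy in kJ/m^2.
#' @export
melt_energy <- function(k = ice_constants()) {
  stopifnot(inherits(k, "ice_constants"))
  k$latent_heat * k$ice_density * k$thickness
}

# day-of-year midpoints of months 1..12 (non-leap calendar)
.month_mid_doy <- function() {
  len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  cumsum(len) - len / 2 + 0.5
}

#' Generate lake-ice break-up dates from an energy balance
#'
#' From 1 March onward, daily melt energy proportional to `max(T_day, 0)`
#' (daily temperatures linearly interpolated between mid-month monthly
#' means) is accumulated; the break-up day is the first day on which the
#' cumulative energy reaches [melt_energy()] for the configured ice cover.
#' Solar radiation and albedo are folded into the single proportionality
#' constant `melt_coeff`.  Gaussian observation noise (in days) is added
#' and the result rounded to whole days.  A year whose energy never reaches
#' the threshold by 31 August yields no date (with a warning).
#'
#' @param mt a [monthly_temperature]; months 2..9 must be present.
#' @param k an [ice_constants].
#' @param noise_sd observation noise SD in days.
#' @param melt_coeff kJ/m^2 delivered per positive degree-day.
#' @param seed RNG seed.
#' @param name series label.
#' @return an [annual_series] of day-of-year break-up dates.
#' @export
gen_ice_melt_date <- function(mt, k = ice_constants(), noise_sd = 2,
                              melt_coeff = 1000, seed = NULL,
                              name = "ice_melt") {
  stopifnot(inherits(mt, "monthly_temperature"))
  need <- melt_energy(k)
  mids <- .month_mid_doy()
  days <- 60:243 # 1 March .. 31 August (non-leap)
  lookup <- mt$temp
  names(lookup) <- paste(mt$year, mt$month)
  yrs <- sort(unique(mt$year))
  melt_raw <- vapply(yrs, function(y) {
    Tm <- lookup[paste(y, 1:12)]
    if (anyNA(Tm[2:9])) return(NA_real_)
    Td <- stats::approx(mids, Tm, xout = days, rule = 2)$y
    cum <- cumsum(melt_coeff * pmax(Td, 0))
    hit <- which(cum >= need)
    if (length(hit) == 0L) return(NA_real_)
    days[hit[1L]]
  }, 1)
  noisy <- with_seed(seed, melt_raw + stats::rnorm(length(yrs), 0, noise_sd))
  vals <- round(noisy)
  have_months <- !vapply(yrs, function(y) anyNA(lookup[paste(y, 2:9)]), TRUE)
  never_melted <- is.na(melt_raw) & have_months
  if (any(never_melted))
    warning("ice did not melt by 31 August in ", sum(never_melted),
            " year(s); dates absent", call. = FALSE)
  vals[is.na(melt_raw)] <- NA_real_
  annual_series(yrs, vals, name = name)
}

#' Generate raw tree-ring series with a summer-temperature signal
#'
#' Multiplicative structure on the natural scale:
#' `width_t = A * exp(-age_t / tau) * exp(beta * z_JJA(t)) * exp(e_t)`
#' with `z_JJA` the standardized summer (JJA) mean temperature and `e` an
#' AR(1) log-noise.  Germination years are staggered across the first part
#' of the record; all series run to its end.  All widths are positive by
#' construction.
#'
#' @param mt a [monthly_temperature].
#' @param n_trees number of series.
#' @param A asymptotic juvenile width scale, mm.
#' @param tau age-trend e-folding time, years.
#' @param beta log-width change per 1 SD of summer temperature (0.2 means
#'   a 1-SD-warm summer widens rings by about 22%).
#' @param noise_sd SD of the AR(1) log-noise.
#' @param phi lag-1 correlation of the log-noise.
#' @param latitude site latitude attached to every series.
#' @param species species label.
#' @param id_prefix series id prefix (ids are `<prefix><i>`).
#' @param seed RNG seed.
#' @return a list of [ring_series].
#' @export
gen_tree_rings <- function(mt, n_trees = 20L, A = 2, tau = 150, beta = 0.2,
                           noise_sd = 0.1, phi = 0.3, latitude = 62,
                           species = "PISY", id_prefix = "SYN",
                           seed = NULL) {
  stopifnot(n_trees >= 1L)
  jja <- seasonal_mean(mt, "summer")
  z <- (jja$values - mean(jja$values)) / stats::sd(jja$values)
  yrs <- jja$years
  n <- length(yrs)
  with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      start <- sample.int(max(1L, floor(0.4 * n)), 1L)
      len <- n - start + 1L
      innov <- stats::rnorm(len)
      e <- numeric(len)
      e[1] <- innov[1]
      for (t in seq_len(len)[-1])
        e[t] <- phi * e[t - 1] + sqrt(1 - phi^2) * innov[t]
      age <- seq_len(len)
      w <- A * exp(-age / tau) * exp(beta * z[start:n]) * exp(e * noise_sd)
      ring_series(sprintf("%s%03d", id_prefix, i), yrs[start], w,
                  latitude = latitude, species = species)
    })
  })
}

#' Generate a complete synthetic study
#'
#' A study-shaped fixture with documented ground truth: a monthly
#' temperature record plus a battery of indicators -- three spring plant
#' phenology series (one with a mid-series observation gap), melt and
#' freeze dates for four lakes (one melt series produced by the
#' energy-balance model, the rest linear), a river break-up series, a
#' winter sea-ice extent series, ring-width chronologies built from raw
#' synthetic tree-ring series for a northern and a southern site, latewood
#' density chronologies, and two serially correlated isotope-like series.
#' Start years are staggered and one series has a gap, exercising the
#' complete-case logic downstream.
#'
#' @param seed master seed; all generators draw from sub-seeds derived
#'   from it.
#' @param n_years record length in years (starting 1881).
#' @return a list: `temperature` (a [monthly_temperature]), `indicators`
#'   (named list of [annual_series]), `truth` (data frame with the
#'   generating `season` and, where defined, population `r2` per
#'   indicator), `seed`.
#' @export
gen_study_suite <- function(seed = 1L, n_years = 140L) {
  stopifnot(n_years >= 30L)
  y0 <- 1881L
  yrs <- seq.int(y0, length.out = n_years)
  mt <- gen_monthly_temperature(climate_config(years = yrs,
                                               seed = derive_seed(seed, "climate")))
  lin <- function(name, season, r2, direction, phi = 0, intercept = 0)
    gen_linear_indicator(mt, season, r2 = r2, direction = direction,
                         phi = phi, intercept = intercept,
                         seed = derive_seed(seed, name), name = name)
  ind <- list()
  add <- function(s, from = NULL, drop = NULL) {
    tr <- attr(s, "truth")
    if (!is.null(from) || !is.null(drop))
      s <- series_window(s, from = from, drop = drop)
    attr(s, "truth") <- tr
    ind[[s$name]] <<- s
  }
  # plant phenology: warm springs -> earlier dates
  add(lin("birch_budburst", "spring", 0.65, -1, intercept = 140), from = y0 + 2L)
  add(lin("bird_cherry_flowering", "spring", 0.70, -1, intercept = 155))
  add(lin("rowan_flowering", "spring", 0.60, -1, intercept = 165),
      drop = 1941:1945)
  # lake and river ice break-up
  add(gen_ice_melt_date(mt, ice_constants(), noise_sd = 3,
                        seed = derive_seed(seed, "nasijarvi_melt"),
                        name = "nasijarvi_melt"))
  add(lin("saimaa_melt", "spring", 0.55, -1, intercept = 130))
  add(lin("kallavesi_melt", "spring", 0.50, -1, intercept = 128))
  add(lin("oulujarvi_melt", "spring", 0.48, -1, intercept = 133))
  add(lin("tornionjoki_breakup", "spring", 0.45, -1, phi = 0.3,
          intercept = 125))
  # freeze-up: warm autumns -> later dates
  add(lin("nasijarvi_freeze", "autumn", 0.60, +1, intercept = 330))
  add(lin("oulujarvi_freeze", "autumn", 0.65, +1, intercept = 320))
  add(lin("kallavesi_freeze", "autumn", 0.60, +1, intercept = 325))
  add(lin("saimaa_freeze", "autumn", 0.50, +1, intercept = 340))
  # sea-ice extent: cold winters -> larger extent
  add(lin("baltic_ice_extent", "winter", 0.70, -1, intercept = 180))
  # tree rings: raw series -> chronologies (stronger signal in the north)
  rw_n <- gen_tree_rings(mt, n_trees = 20L, beta = 0.25, noise_sd = 0.15,
                         latitude = 68, id_prefix = "N",
                         seed = derive_seed(seed, "rings_north"))
  rw_s <- gen_tree_rings(mt, n_trees = 20L, beta = 0.08, noise_sd = 0.20,
                         latitude = 62, id_prefix = "S",
                         seed = derive_seed(seed, "rings_south"))
  ch_n <- build_chronology(rw_n, min_depth = 5L, name = "pine_rw_north")
  ch_s <- build_chronology(rw_s, min_depth = 5L, name = "pine_rw_south")
  add(ch_n$index)
  add(ch_s$index)
  # latewood density and isotope-like chronologies (direct generation)
  add(lin("pine_mxd_north", "summer", 0.40, +1, intercept = 0.9),
      from = y0 + 14L)
  add(lin("spruce_mxd_south", "summer", 0.32, +1, intercept = 0.85),
      from = y0 + 14L)
  add(lin("pine_d13c_north", "summer", 0.22, +1, phi = 0.45,
          intercept = -24), from = y0 + 20L)
  add(lin("oak_d13c_south", "summer", 0.08, +1, phi = 0.50,
          intercept = -25), from = y0 + 20L)
  truth <- data.frame(
    name = names(ind),
    season = vapply(names(ind), function(nm) {
      tr <- attr(ind[[nm]], "truth")
      if (!is.null(tr)) tr$season
      else if (grepl("_rw_", nm)) "summer"
      else "spring" # energy-balance melt dates
    }, ""),
    r2 = vapply(names(ind), function(nm) {
      tr <- attr(ind[[nm]], "truth")
      if (!is.null(tr)) tr$r2 else NA_real_
    }, 1),
    row.names = NULL)
  list(temperature = mt, indicators = ind, truth = truth,
       raw_rings = list(north = rw_n, south = rw_s), seed = seed)
}
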