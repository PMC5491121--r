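#' Study configuration
#'
#' Everything needed to run (and bit-identically re-run) a full reliability
#' study: the data source, the seasons and model families to evaluate, the
#' cross-validation layout and the master seed.
#'
#' @param synthetic logical; `TRUE` generates the data with
#'   [gen_study_suite()] under `seed`.
#' @param indicator_paths named character vector of annual CSV files (used
#'   when `synthetic = FALSE`).
#' @param temperature_path monthly temperature CSV (wide or long; used when
#'   `synthetic = FALSE`).
#' @param seasons season labels to evaluate.
#' @param combination optional character vector naming a fixed indicator
#'   combination to evaluate per season (e.g. the tree-ring proxies:
#'   isotopes + density + ring width).
#' @param repeats outer CV repeats.
#' @param inner_folds,inner_repeats inner model-size CV layout.
#' @param bootstrap_B bootstrap replicates (>= 100).
#' @param annual_lag for the annual season, also offer each indicator's
#'   previous-year value as a candidate (lag-1 columns), reflecting that two
#'   consecutive years of indicator data inform an annual mean.
#' @param n_years record length for the synthetic suite.
#' @param seed master seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(synthetic = TRUE, indicator_paths = NULL,
                         temperature_path = NULL,
                         seasons = c("spring", "summer", "autumn", "winter",
                                     "annual"),
                         combination = NULL,
                         repeats = 50L, inner_folds = 5L, inner_repeats = 5L,
                         bootstrap_B = 10000L, annual_lag = 1L,
                         n_years = 140L, seed = 1L) {
  stopifnot(repeats >= 1L, bootstrap_B >= 100L)
  bad <- setdiff(seasons, seasons())
  if (length(bad)) stop("unknown season(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!synthetic && (is.null(indicator_paths) || is.null(temperature_path)))
    stop("non-synthetic studies need 'indicator_paths' and 'temperature_path'",
         call. = FALSE)
  structure(list(synthetic = synthetic, indicator_paths = indicator_paths,
                 temperature_path = temperature_path, seasons = seasons,
                 combination = combination, repeats = as.integer(repeats),
                 inner_folds = as.integer(inner_folds),
                 inner_repeats = as.integer(inner_repeats),
                 bootstrap_B = as.integer(bootstrap_B),
                 annual_lag = as.integer(annual_lag),
                 n_years = as.integer(n_years), seed = as.integer(seed)),
            class = "study_config")
}

.estimate_row <- function(season, est) {
  data.frame(season = season, model = est$spec$kind, label = est$spec$label,
             reliability = est$reliability,
             reliability_lo = est$ci_reliability[1],
             reliability_hi = est$ci_reliability[2],
             rmse = est$rmse, rmse_lo = est$ci_rmse[1],
             rmse_hi = est$ci_rmse[2], n_years = est$n_years)
}

#' Run a full reliability study
#'
#' For every requested season: aligns all indicators with the seasonal (or
#' annual) mean temperature, evaluates every single-indicator model, the
#' optional fixed combination, the full model (all indicators) and the LARS
#' model, and writes the reports:
#'
#' * `reliability_table.csv` -- one row per season x model family with
#'   reliability, RMSE and their bootstrap confidence intervals (the
#'   best-single row is the maximum over the single-indicator rows, which
#'   are all reported in the grid file);
#' * `single_reliability_grid.csv` -- indicator x season grid of
#'   single-indicator reliabilities;
#' * `selection_frequencies.csv` -- per season, each variable's frequency
#'   across the individual LARS models;
#' * `skipped.csv` -- model/season combinations that could not be evaluated,
#'   with the reason (these are logged and skipped, not fatal);
#' * `manifest.json` -- the full configuration, seeds and package version,
#'   sufficient to re-run bit-identically.
#'
#' @param cfg a [study_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the report data frames and the per-season
#'   `reliability_estimate` objects.
#' @export
run_study <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (cfg$synthetic) {
    suite <- gen_study_suite(seed = cfg$seed, n_years = cfg$n_years)
    mt <- suite$temperature
    indicators <- suite$indicators
  } else {
    indicators <- lapply(names(cfg$indicator_paths), function(nm)
      read_annual_csv(cfg$indicator_paths[[nm]], name = nm))
    names(indicators) <- names(cfg$indicator_paths)
    mt <- read_monthly_csv(cfg$temperature_path)
  }
  if (!is.null(cfg$combination)) {
    missing_comb <- setdiff(cfg$combination, names(indicators))
    if (length(missing_comb))
      stop("combination refers to unknown indicator(s): ",
           paste(missing_comb, collapse = ", "), call. = FALSE)
  }
  rows <- list(); grid <- list(); selfreq <- list(); skipped <- list()
  estimates <- list()
  for (season in cfg$seasons) {
    resp <- seasonal_mean(mt, season)
    m <- align(indicators, resp)
    if (season == "annual" && cfg$annual_lag >= 1L)
      m <- add_lags(m, names(indicators), max_lag = cfg$annual_lag)
    specs <- list()
    for (nm in names(indicators))
      specs[[paste0("single:", nm)]] <-
        model_spec("single", nm, season = season, label = paste0("single:", nm))
    if (!is.null(cfg$combination))
      specs[["combination"]] <- model_spec("fixed_set", cfg$combination,
                                           season = season,
                                           label = "combination")
    specs[["full"]] <- model_spec("fixed_set", NULL, season = season,
                                  label = "full")
    specs[["lars"]] <- model_spec("lars", NULL, season = season,
                                  label = "lars")
    season_est <- list()
    for (lab in names(specs)) {
      est <- tryCatch(
        evaluate_reliability(specs[[lab]], m, repeats = cfg$repeats,
                             seed = derive_seed(cfg$seed,
                                                paste(season, lab, sep = "|")),
                             bootstrap_B = cfg$bootstrap_B,
                             inner_folds = cfg$inner_folds,
                             inner_repeats = cfg$inner_repeats),
        error = function(e) e)
      if (inherits(est, "error")) {
        message("skipping ", season, "/", lab, ": ", conditionMessage(est))
        skipped[[length(skipped) + 1L]] <-
          data.frame(season = season, model = lab,
                     reason = conditionMessage(est))
        next
      }
      season_est[[lab]] <- est
      if (startsWith(lab, "single:")) {
        grid[[length(grid) + 1L]] <-
          data.frame(indicator = sub("^single:", "", lab), season = season,
                     reliability = est$reliability)
      } else {
        rows[[length(rows) + 1L]] <- .estimate_row(season, est)
      }
      if (lab == "lars" && length(est$selection_freq))
        selfreq[[length(selfreq) + 1L]] <-
          data.frame(season = season, variable = names(est$selection_freq),
                     frequency = as.numeric(est$selection_freq))
    }
    # best single-indicator model for the season's summary row
    singles <- season_est[startsWith(names(season_est), "single:")]
    if (length(singles)) {
      best <- singles[[which.max(vapply(singles, function(e) e$reliability, 1))]]
      r <- .estimate_row(season, best)
      r$model <- "best_single"
      rows[[length(rows) + 1L]] <- r
    }
    estimates[[season]] <- season_est
  }
  tab <- do.call(rbind, rows)
  grid_df <- do.call(rbind, grid)
  sf_df <- if (length(selfreq)) do.call(rbind, selfreq)
           else data.frame(season = character(0), variable = character(0),
                           frequency = numeric(0))
  sk_df <- if (length(skipped)) do.call(rbind, skipped)
           else data.frame(season = character(0), model = character(0),
                           reason = character(0))
  .write_report <- function(df, file) {
    num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE,
                     quote = FALSE)
  }
  .write_report(tab, "reliability_table.csv")
  .write_report(grid_df, "single_reliability_grid.csv")
  .write_report(sf_df, "selection_frequencies.csv")
  .write_report(sk_df, "skipped.csv")
  manifest <- list(config = unclass(cfg),
                   package = "proxyrel",
                   package_version = as.character(utils::packageVersion("proxyrel")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(table = tab, grid = grid_df, selection_frequencies = sf_df,
                 skipped = sk_df, estimates = estimates))
}
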