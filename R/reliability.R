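#' Reliability of a temperature signal
#'
#' The package's central statistic: one minus the ratio of the unexplained
#' variance to the variance of the observed temperatures, computed over
#' validation-only predictions.  It coincides with the familiar coefficient
#' of determination when evaluated in-sample, but because it is computed on
#' data never used in training it can be negative: a model worse than the
#' validation mean.
#'
#' @param obs observed values (>= 3, non-constant).
#' @param pred predictions for the same years.
#' @return a scalar <= 1 (possibly negative).
#' @export
reliability_score <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  if (length(obs) < 3L) stop("need >= 3 evaluated years", call. = FALSE)
  if (anyNA(obs) || anyNA(pred)) stop("missing values in obs/pred", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("observed values have zero variance", call. = FALSE)
  1 - sum((obs - pred)^2) / ss_tot
}

#' Random k-fold partition of years
#'
#' Years are assigned to folds uniformly at random ("non-consecutive":
#' no temporal blocking), with fold sizes differing by at most one.
#'
#' @param years vector of years (length >= k).
#' @param k number of folds.
#' @param seed RNG seed; the same seed always gives the same partition.
#' @return an object of class `cv_split`: `assignment` maps each year to a
#'   fold index in `0..k-1`.
#' @export
make_folds <- function(years, k = 5L, seed = NULL) {
  n <- length(years)
  if (n < k) stop("cannot make ", k, " folds from ", n, " years", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold <- rep(seq_len(k) - 1L, length.out = n)  # sizes differ by <= 1
  assignment <- integer(n)
  assignment[perm] <- fold
  structure(list(assignment = stats::setNames(assignment, years),
                 k = as.integer(k), seed = seed),
            class = "cv_split")
}

#' Model specification
#'
#' Declares which model family is evaluated over which candidate variables:
#' `"single"` (simple regression on one indicator), `"fixed_set"` (ordinary
#' multiple regression on a fixed combination; with all candidates this is
#' the "full" model) or `"lars"` (least-angle regression with the number of
#' variables chosen by inner cross-validation).
#'
#' @param kind one of `"single"`, `"fixed_set"`, `"lars"`.
#' @param variables candidate variable labels (matrix column labels, e.g.
#'   `"budburst"` or `"budburst_lag1"`); `NULL` means all columns of the
#'   matrix at evaluation time.  `"single"` requires exactly one.
#' @param season optional season label carried along for reporting.
#' @param label optional display label.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(kind = c("single", "fixed_set", "lars"),
                       variables = NULL, season = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "single" && (is.null(variables) || length(variables) != 1L))
    stop("a 'single' spec needs exactly one variable", call. = FALSE)
  structure(list(kind = kind, variables = variables, season = season,
                 label = label %||%
                   paste0(kind, if (kind == "single") paste0(":", variables))),
            class = "model_spec")
}

# Drop zero-variance columns (can arise in small training subsets).
.nonconstant_cols <- function(X) {
  which(apply(X, 2L, function(col) stats::sd(col) > 0))
}

#' Choose the LAR model size by inner repeated cross-validation
#'
#' Within one (outer) training set, runs `repeats` rounds of `folds`-fold
#' cross-validation: each inner model is trained on 80% of the outer
#' training rows and scored on the held-out 20%.  For every candidate number
#' of variables k the squared validation errors are summed over all
#' `folds * repeats` fits; the k with the smallest total is returned, ties
#' going to the smaller (more parsimonious) k.
#'
#' @param X_train complete-case design matrix of the outer training set
#'   (>= 10 rows).
#' @param y_train response.
#' @param folds,repeats inner cross-validation layout (5 x 5 gives 25 fits).
#' @param seed RNG seed.
#' @return the selected number of variables (integer >= 0).
#' @export
select_k_inner_cv <- function(X_train, y_train, folds = 5L, repeats = 5L,
                              seed = NULL) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n < 10L) stop("inner CV needs >= 10 training rows, got ", n, call. = FALSE)
  p <- ncol(X_train)
  kmax <- min(p, floor(0.8 * n) - 1L)
  sse <- numeric(kmax + 1L)
  for (r in seq_len(repeats)) {
    fs <- make_folds(seq_len(n), k = folds,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, r))
    for (f in seq_len(folds) - 1L) {
      val <- which(fs$assignment == f)
      tr <- setdiff(seq_len(n), val)
      keep <- .nonconstant_cols(X_train[tr, , drop = FALSE])
      if (length(keep) == 0L) {
        sse <- sse + vapply(0:kmax, function(k)
          sum((y_train[val] - mean(y_train[tr]))^2), 1)
        next
      }
      d <- standardize(X_train[tr, keep, drop = FALSE], y_train[tr])
      path <- lars_path(d)
      len <- length(path$order)
      # predictions at every breakpoint at once (standardized space)
      Xv <- sweep(sweep(X_train[val, keep, drop = FALSE], 2L, d$x_center),
                  2L, d$x_scale, "/")
      Pv <- Xv %*% t(path$beta) + d$y_center
      sse_path <- colSums((y_train[val] - Pv)^2)
      sse <- sse + sse_path[pmin(0:kmax, len) + 1L]
    }
  }
  which.min(sse) - 1L  # ties: which.min takes the first, i.e. smallest k
}

# Fit one model specification on training rows; returns a fitted_model with
# an attribute "k" for lars specs.
fit_spec <- function(spec, X_train, y_train, inner_seed,
                     inner_folds = 5L, inner_repeats = 5L) {
  if (spec$kind %in% c("single", "fixed_set")) {
    return(ols_model(X_train, y_train, colnames(X_train)))
  }
  keep <- .nonconstant_cols(X_train)
  if (length(keep) == 0L)
    return(structure(list(coef = stats::setNames(numeric(0), character(0)),
                          intercept = mean(y_train), k = 0L,
                          variables = character(0)), class = "fitted_model"))
  Xk <- X_train[, keep, drop = FALSE]
  d <- standardize(Xk, y_train)
  path <- lars_path(d)
  k <- select_k_inner_cv(Xk, y_train, folds = inner_folds,
                         repeats = inner_repeats, seed = inner_seed)
  coefficients_at(path, min(k, length(path$order)), d)
}

#' Out-of-fold predictions under repeated five-fold cross-validation
#'
#' The first level of the evaluation scheme.  For each repeat the usable
#' years (complete cases in the spec's candidate variables) are partitioned
#' into five random folds; the model is fitted on four folds and predicts
#' the fifth, so each usable year is predicted exactly once per repeat.
#' The `repeats` predictions per year are averaged into a single
#' validation-prediction series.  For `lars` specs, the model size of every
#' fold fit is chosen by [select_k_inner_cv()] inside that fold's training
#' set.  Years missing any required indicator value receive no prediction
#' and are absent from the result.
#'
#' @param spec a [model_spec].
#' @param m an [align()]ed `indicator_matrix`.
#' @param repeats number of outer cross-validation repeats.
#' @param seed master seed for this evaluation.
#' @param inner_folds,inner_repeats layout of the inner (model-size) CV.
#' @return a list: `averaged` (an [annual_series] of averaged out-of-fold
#'   predictions), `records` (one `prediction_record` per repeat x fold, with
#'   the trained model and its validation predictions), `years`, `obs`.
#' @export
cv_predictions <- function(spec, m, repeats = 50L, seed = NULL,
                           inner_folds = 5L, inner_repeats = 5L) {
  stopifnot(inherits(spec, "model_spec"), inherits(m, "indicator_matrix"))
  vars <- spec$variables %||% column_labels(m)
  rows <- usable_rows(m, vars)
  if (length(rows) < 15L)
    stop("only ", length(rows),
         " usable (complete-case) years; need at least 15", call. = FALSE)
  years_u <- m$years[rows]
  Xu <- m$X[rows, match(vars, column_labels(m)), drop = FALSE]
  colnames(Xu) <- vars
  yu <- m$y[rows]
  n <- length(rows)
  P <- matrix(NA_real_, n, repeats)
  records <- vector("list", repeats * 5L)
  ri <- 0L
  for (r in seq_len(repeats)) {
    fs <- make_folds(years_u, k = 5L,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, r))
    for (f in 0:4) {
      val <- which(fs$assignment == f)
      tr <- setdiff(seq_len(n), val)
      fm <- fit_spec(spec, Xu[tr, , drop = FALSE], yu[tr],
                     inner_seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, sprintf("inner_%d_%d", r, f)),
                     inner_folds = inner_folds, inner_repeats = inner_repeats)
      pr <- predict(fm, Xu[val, , drop = FALSE])
      P[val, r] <- pr
      ri <- ri + 1L
      records[[ri]] <- structure(
        list(repeat_index = r, fold = f, model = fm, k = fm$k,
             kind = spec$kind,
             predictions = stats::setNames(pr, years_u[val])),
        class = "prediction_record")
    }
  }
  stopifnot(!anyNA(P))
  list(averaged = annual_series(years_u, rowMeans(P),
                                name = paste0("predicted_", m$response_name)),
       records = records, years = years_u, obs = yu, P = P)
}

#' Percentile bootstrap confidence intervals for reliability and RMSE
#'
#' Resamples (observation, prediction) year-pairs with replacement and
#' recomputes the reliability statistic and RMSE on each replicate;
#' replicates whose resampled observations are constant (reliability
#' undefined) are redrawn.
#'
#' @param obs,pred paired series, length >= 10.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @return a list with `reliability` and `rmse`, each a 2-vector of the 2.5%
#'   and 97.5% percentiles.
#' @export
bootstrap_ci <- function(obs, pred, B = 10000L, seed = NULL) {
  n <- length(obs)
  stopifnot(length(pred) == n)
  if (n < 10L) stop("bootstrap needs >= 10 paired years", call. = FALSE)
  with_seed(seed, {
    rel <- rmse <- rep(NA_real_, B)
    todo <- seq_len(B)
    while (length(todo)) {
      idx <- matrix(sample.int(n, n * length(todo), replace = TRUE), nrow = n)
      ob <- matrix(obs[idx], nrow = n)
      pb <- matrix(pred[idx], nrow = n)
      mb <- colMeans(ob)
      ss_tot <- colSums(ob^2) - n * mb^2
      ss_res <- colSums((ob - pb)^2)
      ok <- ss_tot > .Machine$double.eps * n
      rel[todo[ok]] <- 1 - ss_res[ok] / ss_tot[ok]
      rmse[todo[ok]] <- sqrt(ss_res[ok] / n)
      todo <- todo[!ok]
    }
    list(reliability = unname(stats::quantile(rel, c(0.025, 0.975))),
         rmse = unname(stats::quantile(rmse, c(0.025, 0.975))))
  })
}

#' Selection frequency of each variable across the individual LARS models
#'
#' @param records `prediction_record`s from a `lars` evaluation (one model
#'   per repeat x fold, e.g. 250 for 50 repeats of 5-fold CV).
#' @return named numeric vector: for each candidate variable, the fraction
#'   of models whose selected set contains it.
#' @export
selection_frequency <- function(records) {
  stopifnot(length(records) >= 1L)
  kinds <- vapply(records, function(r) r$kind, "")
  if (any(kinds != "lars"))
    stop("selection frequencies are defined for lars records only", call. = FALSE)
  sel <- lapply(records, function(r) r$model$variables)
  tab <- table(unlist(sel))
  freq <- as.numeric(tab) / length(records)
  stats::setNames(freq, names(tab))
}

#' Evaluate the reliability of a temperature signal
#'
#' The package's main estimator.  Runs the two-level repeated
#' cross-validation scheme ([cv_predictions()]), scores the averaged
#' out-of-fold prediction series against the observed temperatures with
#' [reliability_score()], and attaches percentile bootstrap confidence
#' intervals ([bootstrap_ci()]).  For `lars` specs the per-variable
#' selection frequencies over all individual models are included.
#'
#' @param spec a [model_spec].
#' @param m an [align()]ed `indicator_matrix`.
#' @param repeats outer CV repeats (50 gives each year 50 averaged
#'   out-of-fold predictions).
#' @param seed master seed; fixes folds, inner CV and bootstrap.
#' @param bootstrap_B bootstrap replicates for the confidence intervals.
#' @param inner_folds,inner_repeats inner model-size CV layout (lars only).
#' @return an object of class `reliability_estimate` with elements `spec`,
#'   `reliability`, `rmse`, `ci_reliability`, `ci_rmse`, `n_years`,
#'   `selection_freq` (lars only), `prediction` (averaged series),
#'   `observed`, `repeat_reliability` (per-repeat diagnostic) and `records`.
#' @examples
#' suite <- gen_study_suite(seed = 1, n_years = 60)
#' m <- align(suite$indicators["birch_budburst"],
#'            seasonal_mean(suite$temperature, "spring"))
#' est <- evaluate_reliability(model_spec("single", "birch_budburst"), m,
#'                             repeats = 10, seed = 1, bootstrap_B = 500)
#' print(est)
#' @export
evaluate_reliability <- function(spec, m, repeats = 50L, seed = NULL,
                                 bootstrap_B = 10000L,
                                 inner_folds = 5L, inner_repeats = 5L) {
  cv <- cv_predictions(spec, m, repeats = repeats, seed = seed,
                       inner_folds = inner_folds, inner_repeats = inner_repeats)
  obs <- cv$obs
  pred <- cv$averaged$values
  rel <- reliability_score(obs, pred)
  rmse <- sqrt(mean((obs - pred)^2))
  ci <- bootstrap_ci(obs, pred, B = bootstrap_B,
                     seed = if (is.null(seed)) NULL
                            else derive_seed(seed, "bootstrap"))
  per_rep <- apply(cv$P, 2L, function(col) reliability_score(obs, col))
  structure(list(spec = spec,
                 reliability = rel, rmse = rmse,
                 ci_reliability = ci$reliability, ci_rmse = ci$rmse,
                 n_years = length(obs),
                 selection_freq = if (spec$kind == "lars")
                   selection_frequency(cv$records),
                 prediction = cv$averaged,
                 observed = annual_series(cv$years, obs,
                                          name = m$response_name),
                 repeat_reliability = per_rep,
                 records = cv$records,
                 repeats = repeats, seed = seed),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("Reliability of temperature signal (%s%s)\n", x$spec$kind,
              if (!is.null(x$spec$season)) paste0(", ", x$spec$season) else ""))
  cat(sprintf("  reliability: %.3f  (95%% CI %.3f-%.3f)\n",
              x$reliability, x$ci_reliability[1], x$ci_reliability[2]))
  cat(sprintf("  RMSE:        %.3f  (95%% CI %.3f-%.3f)\n",
              x$rmse, x$ci_rmse[1], x$ci_rmse[2]))
  cat(sprintf("  %d years evaluated, %d CV repeats\n", x$n_years, x$repeats))
  invisible(x)
}

#' @export
summary.reliability_estimate <- function(object, ...) {
  print(object)
  cat(sprintf("  per-repeat reliability (diagnostic): mean %.3f, range %.3f-%.3f\n",
              mean(object$repeat_reliability),
              min(object$repeat_reliability), max(object$repeat_reliability)))
  if (!is.null(object$selection_freq)) {
    cat("  selection frequencies:\n")
    sf <- sort(object$selection_freq, decreasing = TRUE)
    for (nm in names(sf)) cat(sprintf("    %-30s %.2f\n", nm, sf[[nm]]))
  }
  invisible(object)
}

#' Plot observed and cross-validated predicted temperatures
#'
#' @param x a `reliability_estimate`.
#' @param ... passed to [plot()].
#' @export
plot.reliability_estimate <- function(x, ...) {
  yrs <- x$observed$years
  plot(yrs, x$observed$values, type = "l", col = "red3",
       xlab = "year", ylab = "temperature (degrees C)",
       main = sprintf("%s: reliability %.2f", x$spec$label, x$reliability), ...)
  graphics::lines(yrs, x$prediction$values, col = "black")
  graphics::legend("topleft", legend = c("observed", "predicted (CV)"),
                   col = c("red3", "black"), lty = 1, bty = "n")
  invisible(x)
}
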