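# The cross-validation evaluation engine and the reliability statistic.

test_that("reliability_score matches its definition", {
  obs <- c(1, 2, 3)
  expect_equal(reliability_score(obs, obs), 1)
  expect_equal(reliability_score(obs, rep(mean(obs), 3)), 0)
  expect_equal(reliability_score(obs, c(1, 1, 3)), 0.5)
  # invariant to a common additive shift
  set.seed(1)
  o <- rnorm(20); p <- rnorm(20)
  expect_equal(reliability_score(o + 5, p + 5), reliability_score(o, p))
  expect_error(reliability_score(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(reliability_score(1:2, 1:2), ">= 3")
})

test_that("make_folds gives balanced, seed-reproducible random partitions", {
  f10 <- make_folds(1:10, k = 5, seed = 3)
  expect_equal(sort(unique(f10$assignment)), 0:4)
  expect_true(all(table(f10$assignment) == 2))
  f12 <- make_folds(1:12, k = 5, seed = 3)
  expect_equal(sort(as.integer(table(f12$assignment))), c(2L, 2L, 2L, 3L, 3L))
  expect_identical(make_folds(1:12, 5, seed = 9)$assignment,
                   make_folds(1:12, 5, seed = 9)$assignment)
  expect_false(identical(make_folds(1:12, 5, seed = 9)$assignment,
                         make_folds(1:12, 5, seed = 10)$assignment))
  expect_error(make_folds(1:4, 5), "cannot make 5 folds")
})

test_that("inner CV picks a sparse model when the truth is sparse", {
  # with 2 strong signals among 10 candidates, the selected size always
  # covers the true variables and usually stays well below saturation
  # (minimum-SSE selection retains some mildly overfitting extra variables;
  # an independent reference implementation shows the same spread)
  picks <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(100 * 10), 100, 10)
      y <- 2 * X[, 3] - 1.5 * X[, 7] + rnorm(100, 0, 0.5)
    })
    select_k_inner_cv(X, y, seed = seed)
  }, 1L)
  expect_true(all(picks >= 2))
  expect_lte(stats::median(picks), 7)
  # pure noise: the intercept-only model wins most of the time
  picks0 <- vapply(1:20, function(seed) {
    withr::with_seed(seed + 100, {
      X <- matrix(rnorm(100 * 10), 100, 10)
      y <- rnorm(100)
    })
    select_k_inner_cv(X, y, seed = seed)
  }, 1L)
  expect_gt(mean(picks0 == 0), 0.5)
  # determinism
  X <- withr::with_seed(5, matrix(rnorm(200), 50, 4))
  y <- withr::with_seed(6, rnorm(50))
  expect_identical(select_k_inner_cv(X, y, seed = 11),
                   select_k_inner_cv(X, y, seed = 11))
})

test_that("cv_predictions covers every usable year exactly once per repeat", {
  nm <- noise_matrix(n_years = 40, p = 3, seed = 2)
  cv <- cv_predictions(model_spec("single", "noise1"), nm$m,
                       repeats = 7, seed = 1)
  expect_equal(dim(cv$P), c(40L, 7L))
  expect_false(anyNA(cv$P))
  expect_length(cv$records, 35L)
  # validation folds of one repeat partition the usable years
  rec1 <- Filter(function(r) r$repeat_index == 1, cv$records)
  yrs <- sort(as.integer(unlist(lapply(rec1, function(r) names(r$predictions)))))
  expect_equal(yrs, nm$m$years)
})

test_that("a noise-free linear indicator is predicted almost perfectly", {
  mt <- tiny_climate(seed = 31, years = 1901:1950)
  resp <- seasonal_mean(mt, "spring")
  ind <- gen_linear_indicator(mt, "spring", slope = -3, noise_sd = 1e-9,
                              seed = 1, name = "exact")
  m <- align(list(ind), resp)
  cv <- cv_predictions(model_spec("single", "exact"), m, repeats = 5, seed = 2)
  expect_gt(reliability_score(cv$obs, cv$averaged$values), 0.99)
})

test_that("an unrelated indicator scores near zero (slightly negative)", {
  rels <- vapply(1:20, function(seed) {
    nm <- noise_matrix(n_years = 120, p = 1, seed = seed)
    cv <- cv_predictions(model_spec("single", "noise1"), nm$m,
                         repeats = 10, seed = seed)
    reliability_score(cv$obs, cv$averaged$values)
  }, 1)
  expect_lt(abs(mean(rels)), 0.1)
  expect_lt(mean(rels), 0.05)
})

test_that("years with missing indicator cells receive no prediction", {
  mt <- tiny_climate(seed = 41, years = 1901:1960)
  resp <- seasonal_mean(mt, "spring")
  ind <- gen_linear_indicator(mt, "spring", r2 = 0.6, seed = 3, name = "gappy")
  ind <- series_window(ind, drop = 1921:1925)
  m <- align(list(ind), resp)
  cv <- cv_predictions(model_spec("single", "gappy"), m, repeats = 4, seed = 5)
  expect_false(any(1921:1925 %in% cv$averaged$years))
  expect_equal(length(cv$averaged$years), 55L)
  tiny <- align(list(series_window(ind, to = 1912)), resp)
  expect_error(cv_predictions(model_spec("single", "gappy"), tiny,
                              repeats = 2, seed = 1), "usable")
})

test_that("bootstrap CIs are deterministic, ordered and degenerate-safe", {
  set.seed(8)
  obs <- rnorm(30); pred <- obs + rnorm(30, 0, 0.5)
  ci1 <- bootstrap_ci(obs, pred, B = 2000, seed = 4)
  ci2 <- bootstrap_ci(obs, pred, B = 2000, seed = 4)
  expect_identical(ci1, ci2)
  expect_lt(ci1$reliability[1], ci1$reliability[2])
  expect_lt(ci1$rmse[1], ci1$rmse[2])
  # perfect prediction collapses both intervals
  ci <- bootstrap_ci(obs, obs, B = 500, seed = 1)
  expect_equal(ci$reliability, c(1, 1))
  expect_equal(ci$rmse, c(0, 0))
  expect_error(bootstrap_ci(obs[1:5], pred[1:5]), ">= 10")
})

test_that("bootstrap CI coverage is close to nominal", {
  # population reliability 0.5 by construction; large-sample truth covered
  # by the 95% percentile interval in most replications
  covered <- vapply(1:60, function(seed) {
    withr::with_seed(seed, {
      x <- rnorm(120)
      obs <- x + rnorm(120) # pred explains half the variance
    })
    ci <- bootstrap_ci(obs, x, B = 400, seed = seed)$reliability
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 0.99)
})

test_that("selection frequencies count models containing each variable", {
  mt <- tiny_climate(seed = 51, years = 1901:1960)
  resp <- seasonal_mean(mt, "summer")
  sig <- gen_linear_indicator(mt, "summer", r2 = 0.8, direction = 1,
                              seed = 1, name = "sig")
  noise <- annual_series(resp$years,
                         withr::with_seed(2, rnorm(60)), name = "junk")
  m <- align(list(sig, noise), resp)
  est <- evaluate_reliability(model_spec("lars"), m, repeats = 10, seed = 3,
                              bootstrap_B = 200)
  expect_true(all(est$selection_freq >= 0 & est$selection_freq <= 1))
  expect_gt(est$selection_freq[["sig"]], 0.9)
  freq_manual <- mean(vapply(est$records,
                             function(r) "sig" %in% r$model$variables, TRUE))
  expect_equal(est$selection_freq[["sig"]], freq_manual)
  # frequencies are only defined for lars records
  cv <- cv_predictions(model_spec("single", "sig"), m, repeats = 2, seed = 1)
  expect_error(selection_frequency(cv$records), "lars")
})

test_that("evaluate_reliability is consistent across equivalent specs", {
  nm <- noise_matrix(n_years = 60, p = 2, seed = 9)
  e1 <- evaluate_reliability(model_spec("single", "noise1"), nm$m,
                             repeats = 6, seed = 13, bootstrap_B = 300)
  e2 <- evaluate_reliability(model_spec("fixed_set", "noise1"), nm$m,
                             repeats = 6, seed = 13, bootstrap_B = 300)
  expect_equal(e1$reliability, e2$reliability)
  expect_equal(e1$ci_reliability, e2$ci_reliability)
  # rmse is the root mean squared error of the averaged predictions
  expect_equal(e1$rmse,
               sqrt(mean((e1$observed$values - e1$prediction$values)^2)))
  # bit-reproducible for a fixed seed
  e3 <- evaluate_reliability(model_spec("single", "noise1"), nm$m,
                             repeats = 6, seed = 13, bootstrap_B = 300)
  expect_identical(e1$reliability, e3$reliability)
  expect_identical(e1$prediction$values, e3$prediction$values)
})

test_that("reliability estimates recover known population R-squared", {
  for (rho2 in c(0.5, 0.8)) {
    rels <- vapply(1:8, function(seed) {
      mt <- tiny_climate(seed = derive_seed(seed, "c"),
                         years = seq(1901, length.out = 120))
      resp <- seasonal_mean(mt, "spring")
      ind <- gen_linear_indicator(mt, "spring", r2 = rho2,
                                  seed = derive_seed(seed, "i"), name = "x")
      m <- align(list(ind), resp)
      cv <- cv_predictions(model_spec("single", "x"), m,
                           repeats = 15, seed = seed)
      reliability_score(cv$obs, cv$averaged$values)
    }, 1)
    expect_lt(abs(mean(rels) - rho2), 0.07)
  }
})

test_that("more noise never helps: mean reliability falls as noise grows", {
  mean_rel <- vapply(c(0.5, 2, 5), function(sd_noise) {
    mean(vapply(1:10, function(seed) {
      mt <- tiny_climate(seed = derive_seed(seed, "mono"),
                         years = seq(1901, length.out = 80))
      resp <- seasonal_mean(mt, "spring")
      ind <- gen_linear_indicator(mt, "spring", slope = -3,
                                  noise_sd = sd_noise,
                                  seed = derive_seed(seed, "n"), name = "x")
      m <- align(list(ind), resp)
      cv <- cv_predictions(model_spec("single", "x"), m, repeats = 8,
                           seed = seed)
      reliability_score(cv$obs, cv$averaged$values)
    }, 1))
  }, 1)
  expect_true(all(diff(mean_rel) < 0))
})
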