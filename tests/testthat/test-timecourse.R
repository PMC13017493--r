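quad_series <- function(noise_sd = 0, seed = 1, days = seq(25, 95, length.out = 10)) {
  cp <- curve_params("quadratic", asymptote = 9, peak_day = 70,
                     curvature = 0.004, noise_sd = noise_sd)
  set.seed(seed)
  tibble::tibble(day = days,
                 value = eval_curve(cp, days) + rnorm(length(days), 0, noise_sd))
}

test_that("exact data are recovered by the matching parametric model", {
  s <- quad_series()
  fits <- fit_models(s)
  g <- glance(fits)
  expect_equal(g$rss[g$model == "quadratic"], 0, tolerance = 1e-16)
  expect_equal(g$r_squared[g$model == "quadratic"], 1, tolerance = 1e-12)

  days <- seq(25, 95, length.out = 10)
  cl <- curve_params("logistic", asymptote = 100, midpoint = 38, rate = 0.25)
  sl <- tibble::tibble(day = days, value = eval_curve(cl, days))
  fl <- fit_models(sl)
  p <- tidy(fl)
  expect_equal(p$estimate[p$model == "logistic" & p$term == "midpoint"], 38,
               tolerance = 1e-6)
  expect_equal(p$estimate[p$model == "logistic" & p$term == "asymptote"], 100,
               tolerance = 1e-4)
})

test_that("the quadratic fit solves the normal equations", {
  s <- quad_series(noise_sd = 0.4, seed = 8)
  fits <- fit_models(s)
  X <- cbind(1, s$day, s$day^2)
  beta <- solve(t(X) %*% X, t(X) %*% s$value)
  p <- tidy(fits)
  expect_equal(p$estimate[p$model == "quadratic"], as.numeric(beta),
               tolerance = 1e-8)
})

test_that("fit metrics are internally consistent and match stats::AIC", {
  s <- quad_series(noise_sd = 0.4, seed = 3)
  g <- glance(fit_models(s))
  ok <- g[g$converged, ]
  n <- nrow(s)
  expect_equal(ok$rmse^2 * n, ok$rss, tolerance = 1e-10)
  expect_true(all(ok$mae <= ok$rmse + 1e-12))
  expect_true(all(ok$aic < ok$bic)) # n = 10 > e^2
  expect_true(all(ok$r_squared <= 1))

  # same AIC/BIC constant as the standard lm likelihood
  ref <- lm(value ~ day + I(day^2), data = s)
  expect_equal(g$aic[g$model == "quadratic"], AIC(ref), tolerance = 1e-8)
  expect_equal(g$bic[g$model == "quadratic"], BIC(ref), tolerance = 1e-8)
})

test_that("model selection uses AIC with BIC and RMSE tie-breaks", {
  mk <- function(model, aic, bic, rmse) {
    f <- fake_fit(0:1, c(0, 1))
    f$model <- model
    f$metrics <- tibble::tibble(mae = 0, rss = 0, rmse = rmse,
                                r_squared = 1, aic = aic, bic = bic)
    f$edf <- 3
    f
  }
  fits <- structure(list(a = mk("a", 10, 5, 1), b = mk("b", 20, 1, 1),
                         c = mk("c", 30, 1, 1)), class = "canopy_fits")
  expect_equal(select_model(fits), "a")
  fits2 <- structure(list(a = mk("a", 10, 12, 1), b = mk("b", 10, 11, 1)),
                     class = "canopy_fits")
  expect_equal(select_model(fits2), "b")
  fits3 <- structure(list(a = mk("a", 10, 11, 2), b = mk("b", 10, 11, 1)),
                     class = "canopy_fits")
  expect_equal(select_model(fits3), "b")
})

test_that("a decreasing series fails the growth-logistic but not the others", {
  s <- tibble::tibble(day = seq(10, 100, 10), value = seq(90, 0, -10))
  fits <- fit_models(s)
  expect_false(fits$logistic$converged)
  expect_true(fits$lowess$converged)
  expect_true(fits$quadratic$converged)
  expect_error(fit_models(s[1:3, ]), "4 time points")
})

test_that("peak extraction finds the vertex and flags boundary maxima", {
  d <- seq(30, 90, 0.1)
  pk <- extract_peak(fake_fit(d, 9 - (d - 60)^2 * 0.01))
  expect_equal(pk$peak_day, 60)
  expect_equal(pk$peak_value, 9)
  expect_false(pk$censored)

  rising <- extract_peak(fake_fit(d, 1 / (1 + exp(-0.1 * (d - 60)))))
  expect_equal(rising$peak_day, 90)
  expect_true(rising$censored)
})

test_that("threshold crossings interpolate and report unreachable levels", {
  d <- seq(0, 100, 0.1)
  lin <- fake_fit(d, d) # 0 to 100 linearly
  expect_equal(extract_threshold_crossing(lin, 50), 50)
  expect_equal(extract_threshold_crossing(lin, 99.5), 99.5)

  plateau <- fake_fit(d, pmin(d, 80))
  x <- extract_threshold_crossing(plateau, 99.5)
  expect_true(is.na(x))
  expect_equal(attr(x, "reason"), "never reached")

  expect_error(extract_threshold_crossing(lin, 0), "0, 100")
  expect_error(extract_threshold_crossing(lin, 150), "0, 100")
})

test_that("decline onset detects a sustained drop after the peak", {
  d <- seq(30, 100, 0.1)
  f <- fake_fit(d, ifelse(d <= 79, 0.9, 0.9 - 0.9 * (d - 79)))
  expect_equal(as.numeric(extract_decline_onset(f)), 79, tolerance = 0.2)

  inc <- fake_fit(d, d / 100)
  x <- extract_decline_onset(inc)
  expect_true(is.na(x))
  expect_equal(attr(x, "reason"), "no decline")
})

test_that("extracted days shift with the day axis and scale with the values", {
  s <- quad_series(noise_sd = 0.2, seed = 5)
  base <- extract_traits(dplyr::mutate(s, plot_id = "p", trait = "LAI"))
  shifted <- extract_traits(dplyr::mutate(s, plot_id = "p", trait = "LAI",
                                          day = day + 13))
  expect_equal(shifted$peak_day, base$peak_day + 13, tolerance = 1e-8)
  expect_equal(shifted$peak_value, base$peak_value, tolerance = 1e-8)

  scaled <- extract_traits(dplyr::mutate(s, plot_id = "p", trait = "LAI",
                                         value = value * 2.5))
  expect_equal(scaled$peak_value, base$peak_value * 2.5, tolerance = 1e-8)
  expect_equal(scaled$peak_day, base$peak_day, tolerance = 1e-8)
})

test_that("extract_traits summarises plots and extracts CC thresholds", {
  lay <- generate_layout(1, seed = 2)
  days <- seq(21, 99, 4)
  cc <- curve_params("logistic", asymptote = 100, midpoint = 38, rate = 0.25,
                     noise_sd = 2)
  sim <- simulate_timecourse(lay[1:4, ], cc, days, trait = "CC", seed = 6)
  out <- extract_traits(sim$series)
  expect_equal(nrow(out), 4)
  expect_true(all(!is.na(out$cc50_day)))
  expect_true(all(abs(out$cc50_day - 38) < 3))
  expect_true(all(out$cc50_day <= out$cc100_day, na.rm = TRUE))
})
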