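#' @name timecourse_traits
#' @title Time-course model fitting and temporal-parameter extraction
#'
#' @description
#' Canopy traits measured repeatedly through the season (LAI, canopy
#' coverage, NDVI, plant height, digital biomass) are summarised by fitting
#' three candidate models to each plot's series — LOWESS (local quadratic
#' regression with robustness iterations), a 3-parameter logistic, and a
#' second-degree polynomial — scoring each with MAE, RSS, RMSE, R^2, AIC
#' and BIC, selecting the best by information criterion, and extracting
#' temporal parameters (peak value and day, days to 50%/full canopy
#' coverage, day of decline onset, maximum value) from the fitted curve on
#' a dense day grid.
NULL

gaussian_ic <- function(rss, n, k) {
  # profiled-sigma Gaussian likelihood; k counts the mean-model df, +1 for sigma
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  c(AIC = -2 * ll + 2 * (k + 1), BIC = -2 * ll + log(n) * (k + 1))
}

fit_metrics <- function(obs, fitted, edf) {
  n <- length(obs)
  res <- obs - fitted
  rss <- sum(res^2)
  ic <- gaussian_ic(rss, n, edf)
  tibble::tibble(
    mae = mean(abs(res)),
    rss = rss,
    rmse = sqrt(rss / n),
    r_squared = 1 - rss / sum((obs - mean(obs))^2),
    aic = ic[["AIC"]],
    bic = ic[["BIC"]]
  )
}

new_canopy_fit <- function(model, day, value, fitted_obs, grid, params, edf,
                           converged = TRUE) {
  metrics <- if (converged) fit_metrics(value, fitted_obs, edf) else
    tibble::tibble(mae = NA_real_, rss = NA_real_, rmse = NA_real_,
                   r_squared = NA_real_, aic = NA_real_, bic = NA_real_)
  structure(
    list(model = model, day = day, value = value, fitted = fitted_obs,
         grid = grid, params = params, edf = edf, converged = converged,
         metrics = metrics),
    class = "canopy_fit"
  )
}

failed_fit <- function(model, day, value) {
  new_canopy_fit(model, day, value, fitted_obs = NULL,
                 grid = NULL, params = NULL, edf = NA_real_,
                 converged = FALSE)
}

day_grid <- function(day, step) {
  g <- seq(min(day), max(day), by = step)
  if (tail(g, 1) < max(day)) g <- c(g, max(day))
  g
}

fit_lowess <- function(day, value, span, grid_step, iterations = 3) {
  # short, evenly spaced series make individual local fits near-singular;
  # loess falls back to a pseudoinverse and warns, which is expected here
  fit <- suppressWarnings(loess(
    value ~ day, span = span, degree = 2, family = "symmetric",
    control = stats::loess.control(surface = "direct",
                                   iterations = iterations,
                                   trace.hat = "exact")
  ))
  grid <- day_grid(day, grid_step)
  new_canopy_fit(
    "lowess", day, value,
    fitted_obs = unname(fitted(fit)),
    grid = tibble::tibble(
      day = grid,
      fitted = unname(suppressWarnings(predict(fit, grid)))
    ),
    params = c(span = span),
    edf = fit$trace.hat
  )
}

fit_quadratic <- function(day, value, grid_step) {
  fit <- lm(value ~ day + I(day^2))
  grid <- day_grid(day, grid_step)
  b <- unname(coef(fit))
  new_canopy_fit(
    "quadratic", day, value,
    fitted_obs = unname(fitted(fit)),
    grid = tibble::tibble(day = grid, fitted = b[1] + b[2] * grid + b[3] * grid^2),
    params = c(b0 = b[1], b1 = b[2], b2 = b[3]),
    edf = 3
  )
}

logistic_starts <- function(day, value) {
  a0 <- max(value)
  if (a0 <= 0) a0 <- 1
  half <- a0 / 2
  above <- which(value >= half)
  m0 <- if (length(above) > 0) day[above[1]] else median(day)
  r0 <- 4 / max(diff(range(day)) / 4, 1)
  list(
    c(A = a0, m = m0, r = r0),
    c(A = a0 * 1.1, m = m0, r = r0 * 2),
    c(A = a0 * 1.1, m = m0 - diff(range(day)) / 5, r = r0 / 2),
    c(A = a0 * 1.5, m = m0 + diff(range(day)) / 5, r = r0),
    c(A = a0, m = median(day), r = 0.1)
  )
}

fit_logistic <- function(day, value, grid_step, max_starts = 5) {
  if (length(day) < 5) return(failed_fit("logistic", day, value))
  lower <- c(A = 1e-8, m = min(day) - diff(range(day)),
             r = 1e-6)
  upper <- c(A = 10 * max(abs(value)) + 1, m = max(day) + diff(range(day)),
             r = 10)
  best <- NULL
  for (st in head(logistic_starts(day, value), max_starts)) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        value ~ A / (1 + exp(-r * (day - m))),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(cand)) {
      rss <- sum(resid(cand)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = cand, rss = rss)
    }
  }
  if (is.null(best)) return(failed_fit("logistic", day, value))
  p <- coef(best$fit)
  # a rate pinned at its bound means the sigmoid degenerated (no growth signal)
  if (p[["r"]] <= 2e-6 || p[["r"]] >= 10 - 1e-6 ||
      p[["A"]] >= upper[["A"]] - 1e-6) {
    return(failed_fit("logistic", day, value))
  }
  grid <- day_grid(day, grid_step)
  new_canopy_fit(
    "logistic", day, value,
    fitted_obs = unname(fitted(best$fit)),
    grid = tibble::tibble(
      day = grid,
      fitted = p[["A"]] / (1 + exp(-p[["r"]] * (grid - p[["m"]])))
    ),
    params = c(asymptote = p[["A"]], midpoint = p[["m"]], rate = p[["r"]]),
    edf = 3
  )
}

#' Fit the three candidate models to one trait time course
#'
#' @param series Data frame with `day` and `value` columns for a single
#'   plot and trait (extra columns ignored). At least 4 points; the
#'   logistic needs 5 and is flagged non-converged below that.
#' @param span LOWESS span (fraction of points per local fit).
#' @param grid_step Dense evaluation grid step in days (also the
#'   resolution of extracted days).
#' @return An object of class `canopy_fits`: a named list of `canopy_fit`
#'   objects (`lowess`, `logistic`, `quadratic`), each carrying fitted
#'   values on the dense grid, parameters, effective degrees of freedom,
#'   and the six fit metrics. A non-converged logistic is reported, not
#'   raised. Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' cp <- curve_params("quadratic", asymptote = 9, peak_day = 70,
#'                    curvature = 0.004)
#' s <- tibble::tibble(day = seq(25, 95, 10),
#'                     value = eval_curve(cp, seq(25, 95, 10)))
#' glance(fit_models(s))
#' @export
fit_models <- function(series, span = 0.5, grid_step = 0.1) {
  stopifnot(all(c("day", "value") %in% names(series)))
  series <- dplyr::arrange(series, .data$day)
  day <- series$day
  value <- series$value
  if (length(day) < 4) abort("At least 4 time points are required.")
  if (any(diff(day) <= 0)) abort("`day` must be strictly increasing.")
  fits <- list(
    lowess = tryCatch(fit_lowess(day, value, span, grid_step),
                      error = function(e) failed_fit("lowess", day, value)),
    logistic = fit_logistic(day, value, grid_step),
    quadratic = fit_quadratic(day, value, grid_step)
  )
  structure(fits, class = "canopy_fits")
}

#' Select the best time-course model
#'
#' @param fits A `canopy_fits` object from [fit_models()].
#' @param rule Selection metric; `"aic"` (default) picks the lowest AIC
#'   among converged fits, breaking ties by lowest BIC, then lowest RMSE.
#' @return The name of the selected model.
#' @export
select_model <- function(fits, rule = c("aic", "bic", "rmse")) {
  rule <- match.arg(rule)
  ok <- purrr::keep(fits, "converged")
  if (length(ok) == 0) abort("No model converged.")
  g <- glance(structure(ok, class = "canopy_fits"))
  keys <- switch(rule,
    aic = list(g$aic, g$bic, g$rmse),
    bic = list(g$bic, g$aic, g$rmse),
    rmse = list(g$rmse, g$aic, g$bic)
  )
  g$model[order(keys[[1]], keys[[2]], keys[[3]])[1]]
}

#' @method glance canopy_fits
#' @export
glance.canopy_fits <- function(x, ...) {
  purrr::map_dfr(x, function(f) {
    dplyr::bind_cols(
      tibble::tibble(model = f$model, converged = f$converged, edf = f$edf),
      f$metrics
    )
  })
}

#' @method tidy canopy_fits
#' @export
tidy.canopy_fits <- function(x, ...) {
  purrr::map_dfr(x, function(f) {
    if (is.null(f$params)) {
      return(tibble::tibble(model = f$model, term = NA_character_,
                            estimate = NA_real_))
    }
    tibble::tibble(model = f$model, term = names(f$params),
                   estimate = unname(f$params))
  })
}

#' Extract the fitted peak
#'
#' @param fit A converged `canopy_fit`.
#' @return One-row tibble: `peak_value`, `peak_day` (argmax over the dense
#'   grid, to the grid resolution), and `censored` (`TRUE` when the
#'   maximum sits on the first or last grid day, i.e. no interior peak was
#'   observed within the sampling window).
#' @export
extract_peak <- function(fit) {
  stopifnot(inherits(fit, "canopy_fit"), fit$converged)
  i <- which.max(fit$grid$fitted)
  tibble::tibble(
    peak_value = fit$grid$fitted[i],
    peak_day = fit$grid$day[i],
    censored = i == 1L || i == nrow(fit$grid)
  )
}

#' Day a fitted percentage trait first crosses a threshold
#'
#' Intended for canopy coverage on a 0-100 scale. Full closure (CC100) is
#' operationalised as the 99.5% crossing, since a fitted asymptote never
#' literally attains 100.
#'
#' @param fit A converged `canopy_fit`.
#' @param threshold_percent Threshold in `(0, 100]`.
#' @return The crossing day (linear interpolation between grid points), or
#'   `NA` with attribute `reason = "never reached"`.
#' @export
extract_threshold_crossing <- function(fit, threshold_percent) {
  stopifnot(inherits(fit, "canopy_fit"), fit$converged)
  if (threshold_percent <= 0 || threshold_percent > 100) {
    abort("`threshold_percent` must be in (0, 100].")
  }
  f <- fit$grid$fitted
  d <- fit$grid$day
  i <- which(f >= threshold_percent)[1]
  if (is.na(i)) {
    return(structure(NA_real_, reason = "never reached"))
  }
  if (i == 1L) return(d[1])
  # linear interpolation within the bracketing grid cell
  d[i - 1] + (d[i] - d[i - 1]) * (threshold_percent - f[i - 1]) / (f[i] - f[i - 1])
}

#' Day a fitted curve starts its sustained decline
#'
#' Finds the smallest day at or after the fitted peak where the curve has
#' dropped below `(1 - delta)` of the peak value and stays below it for at
#' least `run` consecutive grid days — a proxy for the onset of senescence
#' (e.g. NDVI decline).
#'
#' @param fit A converged `canopy_fit`.
#' @param delta Relative drop defining "declined". The default 3% is the
#'   smallest drop reliably distinguishable from the LOWESS smoother's own
#'   bias around a plateau-to-decline corner at seasonal sampling
#'   densities; smaller values date the onset systematically early.
#' @param run Number of consecutive grid days the drop must persist.
#' @return The onset day, or `NA` with attribute `reason = "no decline"`.
#' @export
extract_decline_onset <- function(fit, delta = 0.03, run = 3L) {
  stopifnot(inherits(fit, "canopy_fit"), fit$converged, delta > 0)
  pk <- extract_peak(fit)
  f <- fit$grid$fitted
  d <- fit$grid$day
  thr <- (1 - delta) * pk$peak_value
  start <- which(d >= pk$peak_day)[1]
  below <- f < thr
  n <- length(f)
  for (i in start:n) {
    j <- min(i + run - 1L, n)
    if (all(below[i:j])) return(d[i])
  }
  structure(NA_real_, reason = "no decline")
}

#' Fit, select and summarise time courses for many plots
#'
#' Maps [fit_models()] over every `plot_id` x `trait` series in a long
#' table, selects a model per series, and extracts the temporal summary:
#' peak value/day, days to 50% and full canopy coverage (traits on a
#' 0-100 scale, by default `CC`), decline-onset day, and maximum value.
#'
#' @param series Long table: `plot_id`, `trait`, `day`, `value`.
#' @param model `"auto"` (information-criterion selection) or one of
#'   `"lowess"`, `"logistic"`, `"quadratic"`.
#' @param percent_traits Traits on a 0-100 scale for which threshold
#'   crossings are extracted.
#' @param cc100_threshold Percent crossing reported as full closure.
#' @inheritParams fit_models
#' @inheritParams extract_decline_onset
#' @return A tibble, one row per plot x trait: `model_used`, `peak_value`,
#'   `peak_day`, `peak_censored`, `cc50_day`, `cc100_day`,
#'   `decline_onset_day`, `max_value`.
#' @export
extract_traits <- function(series, model = "auto",
                           percent_traits = "CC", cc100_threshold = 99.5,
                           span = 0.5, grid_step = 0.1, delta = 0.03) {
  stopifnot(all(c("plot_id", "trait", "day", "value") %in% names(series)))
  series |>
    dplyr::group_by(.data$plot_id, .data$trait) |>
    dplyr::group_modify(function(g, key) {
      fits <- fit_models(g, span = span, grid_step = grid_step)
      used <- if (model == "auto") select_model(fits) else model
      fit <- fits[[used]]
      if (is.null(fit) || !fit$converged) {
        return(tibble::tibble(
          model_used = used, peak_value = NA_real_, peak_day = NA_real_,
          peak_censored = NA, cc50_day = NA_real_, cc100_day = NA_real_,
          decline_onset_day = NA_real_, max_value = NA_real_
        ))
      }
      pk <- extract_peak(fit)
      is_pct <- key$trait %in% percent_traits
      tibble::tibble(
        model_used = used,
        peak_value = pk$peak_value,
        peak_day = pk$peak_day,
        peak_censored = pk$censored,
        cc50_day = if (is_pct) as.numeric(extract_threshold_crossing(fit, 50)) else NA_real_,
        cc100_day = if (is_pct) as.numeric(extract_threshold_crossing(fit, cc100_threshold)) else NA_real_,
        decline_onset_day = as.numeric(extract_decline_onset(fit, delta = delta)),
        max_value = max(fit$grid$fitted)
      )
    }) |>
    dplyr::ungroup()
}

#' @export
print.canopy_fit <- function(x, ...) {
  cat(sprintf("<canopy_fit: %s, %s>\n", x$model,
              if (x$converged) sprintf("edf %.2f, RMSE %.4g", x$edf, x$metrics$rmse)
              else "did not converge"))
  invisible(x)
}

#' Plot a fitted time course
#'
#' @param object A `canopy_fits` object.
#' @param ... Unused.
#' @return A ggplot of the observations with each converged fitted curve.
#' @method autoplot canopy_fits
#' @export
autoplot.canopy_fits <- function(object, ...) {
  obs <- tibble::tibble(day = object[[1]]$day, value = object[[1]]$value)
  curves <- purrr::map_dfr(
    purrr::keep(object, "converged"),
    function(f) dplyr::mutate(f$grid, model = f$model)
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value)) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(y = .data$fitted, colour = .data$model)
    ) +
    ggplot2::labs(x = "Day after planting", y = "Trait value",
                  colour = "Model")
}
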