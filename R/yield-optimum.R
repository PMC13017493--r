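#' @name yield_optimum
#' @title Quadratic peak-LAI versus yield optimum
#'
#' @description
#' Whether yield keeps rising with canopy size or peaks at an intermediate
#' leaf area index is tested by fitting linear and quadratic ordinary
#' least squares models of yield on peak LAI within each stratum
#' (location x spacing), comparing them by AIC, BIC, R^2 and RMSE, and —
#' when the quadratic wins with negative curvature — reporting its vertex
#' `-b1 / (2 b2)` as the yield-maximising (optimal) LAI.
NULL

lai_yield_metrics <- function(fit, n) {
  rss <- sum(resid(fit)^2)
  k <- length(coef(fit))
  ic <- gaussian_ic(rss, n, k)
  y <- fitted(fit) + resid(fit)
  tibble::tibble(
    rss = rss,
    rmse = sqrt(rss / n),
    r_squared = 1 - rss / sum((y - mean(y))^2),
    aic = ic[["AIC"]],
    bic = ic[["BIC"]]
  )
}

#' Fit linear and quadratic LAI-yield models
#'
#' @param data Data frame with the predictor and response columns.
#' @param lai_col,yield_col Column names (default `peak_lai`, `yield`).
#' @return An object of class `lai_yield_fit`: the two `lm` fits, their
#'   comparison metrics, and the observed LAI range. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @examples
#' d <- tibble::tibble(peak_lai = seq(6, 13, length.out = 40),
#'                     yield = 6000 - 40 * (peak_lai - 10)^2)
#' glance(fit_lai_yield(d))
#' @export
fit_lai_yield <- function(data, lai_col = "peak_lai", yield_col = "yield") {
  x <- data[[lai_col]]
  y <- data[[yield_col]]
  if (length(x) < 4) abort("At least 4 observations are required.")
  if (var(x) < .Machine$double.eps) {
    abort("Constant peak-LAI predictor: the design matrix is singular.")
  }
  d <- tibble::tibble(x = x, y = y)
  linear <- lm(y ~ x, data = d)
  quadratic <- lm(y ~ x + I(x^2), data = d)
  structure(
    list(
      linear = linear,
      quadratic = quadratic,
      metrics = dplyr::bind_rows(
        dplyr::mutate(lai_yield_metrics(linear, nrow(d)), model = "linear",
                      .before = 1),
        dplyr::mutate(lai_yield_metrics(quadratic, nrow(d)), model = "quadratic",
                      .before = 1)
      ),
      lai_range = range(x),
      data = d
    ),
    class = "lai_yield_fit"
  )
}

#' Optimal (yield-maximising) peak LAI from the quadratic fit
#'
#' @param fit A `lai_yield_fit`.
#' @return One-row tibble: `optimal_lai` (the vertex `-b1 / (2 b2)`),
#'   `valid` (`TRUE` only when the curvature is negative so the vertex is
#'   a maximum), `extrapolated` (vertex outside the observed LAI range)
#'   and `reason` for invalid estimates.
#' @export
optimal_lai <- function(fit) {
  stopifnot(inherits(fit, "lai_yield_fit"))
  b <- unname(coef(fit$quadratic))
  b1 <- b[2]
  b2 <- b[3]
  if (b2 == 0) {
    return(tibble::tibble(optimal_lai = NA_real_, valid = FALSE,
                          extrapolated = NA, reason = "no curvature"))
  }
  vertex <- -b1 / (2 * b2)
  if (b2 > 0) {
    return(tibble::tibble(optimal_lai = vertex, valid = FALSE,
                          extrapolated = NA,
                          reason = "positive curvature (vertex is a minimum)"))
  }
  tibble::tibble(
    optimal_lai = vertex,
    valid = TRUE,
    extrapolated = vertex < fit$lai_range[1] || vertex > fit$lai_range[2],
    reason = NA_character_
  )
}

#' Compare the linear and quadratic LAI-yield models
#'
#' @param fit A `lai_yield_fit`.
#' @return A list with `table` (per-metric winner; R^2 higher-is-better,
#'   the rest lower-is-better) and `overall` — the AIC pick, with an exact
#'   AIC tie resolved toward the linear model (parsimony).
#' @export
compare_models <- function(fit) {
  stopifnot(inherits(fit, "lai_yield_fit"))
  m <- fit$metrics
  lin <- m[m$model == "linear", ]
  quad <- m[m$model == "quadratic", ]
  winner <- function(metric, lower_better = TRUE) {
    a <- lin[[metric]]
    b <- quad[[metric]]
    if (a == b) return("linear")
    if (xor(a < b, !lower_better)) "linear" else "quadratic"
  }
  table <- tibble::tibble(
    metric = c("aic", "bic", "rmse", "r_squared"),
    linear = c(lin$aic, lin$bic, lin$rmse, lin$r_squared),
    quadratic = c(quad$aic, quad$bic, quad$rmse, quad$r_squared),
    winner = c(winner("aic"), winner("bic"), winner("rmse"),
               winner("r_squared", lower_better = FALSE))
  )
  list(table = table, overall = winner("aic"))
}

#' Per-stratum LAI-yield optimum analysis
#'
#' Fits both models independently within each stratum and reports the
#' comparison and the vertex estimate, mirroring a multi-site,
#' multi-spacing trial analysed one stratum at a time.
#'
#' @param data Data frame with stratum columns plus peak LAI and yield.
#' @param stratify Character vector of stratum columns.
#' @inheritParams fit_lai_yield
#' @return Tibble, one row per stratum: model metrics for both fits,
#'   `preferred` model by AIC, and the `optimal_lai` estimate.
#' @export
lai_yield_by_stratum <- function(data, stratify = c("location", "spacing"),
                                 lai_col = "peak_lai", yield_col = "yield") {
  stratify <- intersect(stratify, names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratify))) |>
    dplyr::group_modify(function(g, key) {
      fit <- fit_lai_yield(g, lai_col = lai_col, yield_col = yield_col)
      cmp <- compare_models(fit)
      opt <- optimal_lai(fit)
      wide <- fit$metrics |>
        tidyr::pivot_wider(names_from = "model",
                           values_from = c("rss", "rmse", "r_squared",
                                           "aic", "bic"))
      dplyr::bind_cols(
        wide,
        tibble::tibble(preferred = cmp$overall),
        opt,
        tibble::tibble(n = nrow(g))
      )
    }) |>
    dplyr::ungroup()
}

#' @method tidy lai_yield_fit
#' @export
tidy.lai_yield_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(model = "linear",
                   term = c("intercept", "lai"),
                   estimate = unname(coef(x$linear))),
    tibble::tibble(model = "quadratic",
                   term = c("intercept", "lai", "lai_squared"),
                   estimate = unname(coef(x$quadratic)))
  )
}

#' @method glance lai_yield_fit
#' @export
glance.lai_yield_fit <- function(x, ...) x$metrics

#' @export
print.lai_yield_fit <- function(x, ...) {
  cat("Peak LAI - yield fits (OLS)\n")
  print(x$metrics)
  invisible(x)
}

#' Plot the LAI-yield relationship
#'
#' @param object A `lai_yield_fit`.
#' @param ... Unused.
#' @return A ggplot of the data with both fitted curves and, when valid,
#'   a vertical line at the optimal LAI.
#' @method autoplot lai_yield_fit
#' @export
autoplot.lai_yield_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(object$lai_range[1], object$lai_range[2],
                                 length.out = 200))
  curves <- dplyr::bind_rows(
    dplyr::mutate(grid, yield = predict(object$linear, grid), model = "linear"),
    dplyr::mutate(grid, yield = predict(object$quadratic, grid),
                  model = "quadratic")
  )
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.6) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$yield, colour = .data$model)) +
    ggplot2::labs(x = "Peak LAI", y = "Yield", colour = "Model")
  opt <- optimal_lai(object)
  if (isTRUE(opt$valid) && !opt$extrapolated) {
    p <- p + ggplot2::geom_vline(xintercept = opt$optimal_lai,
                                 linetype = "dashed")
  }
  p
}
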