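#' @name aci_fit_module
#' @title FvCB photosynthesis model and A-Ci curve fitting
#'
#' @description
#' The Farquhar-von Caemmerer-Berry (FvCB) model for C3 leaves predicts
#' net CO2 assimilation as the minimum of the Rubisco-limited rate
#' `Wc = Vcmax (Ci - G*) / (Ci + Kc (1 + O/Ko))` and the RuBP-regeneration
#' limited rate `Wj = J (Ci - G*) / (4 Ci + 8 G*)`, minus day respiration
#' `Rd`. Mesophyll conductance is treated as infinite, so the intercellular
#' CO2 concentration `Ci` is the substrate concentration and the fitted
#' parameters are apparent (Ci-based) values. Whole curves are fit by
#' residual-sum-of-squares minimisation (the maximum-likelihood estimate
#' under Gaussian error) with a derivative-free simplex search and multiple
#' starts, and estimates are normalised to 25 degrees C with Arrhenius
#' temperature responses.
NULL

#' Rubisco kinetics and temperature-response constants
#'
#' Values at 25 degrees C and Arrhenius activation energies from the
#' in-vivo tobacco calibration of Bernacchi et al. (2001, Plant Cell
#' Environ 24:253-259); the electron-transport activation energy is from
#' the companion calibration (Bernacchi et al. 2003).
#'
#' @param o Oxygen concentration (mmol mol^-1), default 210 (ambient).
#' @return A list of class `aci_kinetics`: `kc25` (µmol mol^-1), `ko25`
#'   (mmol mol^-1), `gamma_star25` (µmol mol^-1), `o`, and activation
#'   energies `ha` (kJ mol^-1) for `kc`, `ko`, `gamma_star`, `vcmax`,
#'   `jmax`, `rd`.
#' @export
bernacchi_kinetics <- function(o = 210) {
  stopifnot(o > 0)
  structure(
    list(
      kc25 = 404.9,
      ko25 = 278.4,
      gamma_star25 = 42.75,
      o = o,
      ha = c(kc = 79.43, ko = 36.38, gamma_star = 37.83,
             vcmax = 65.33, jmax = 43.9, rd = 46.39)
    ),
    class = "aci_kinetics"
  )
}

#' Arrhenius temperature scaling factor relative to 25 degrees C
#'
#' @param ha_kj Activation energy (kJ mol^-1).
#' @param tleaf Leaf temperature (degrees C).
#' @return `exp(ha (Tk - 298.15) / (298.15 R Tk))`; 1 at 25 degrees C.
#' @export
arrhenius_factor <- function(ha_kj, tleaf) {
  tk <- tleaf + 273.15
  exp(ha_kj * 1000 * (tk - 298.15) / (298.15 * 8.314 * tk))
}

#' Normalise a parameter estimate to 25 degrees C
#'
#' @param param_value Estimate at leaf temperature.
#' @param tleaf Leaf temperature (degrees C).
#' @param ha_kj Activation energy for the parameter (kJ mol^-1).
#' @return The estimate divided by its Arrhenius factor at `tleaf`
#'   (identity at 25 degrees C).
#' @export
normalize_25 <- function(param_value, tleaf, ha_kj) {
  if (is.null(ha_kj) || is.na(ha_kj)) {
    abort("No temperature-response coefficient available for this parameter.")
  }
  param_value / arrhenius_factor(ha_kj, tleaf)
}

kinetics_at <- function(kinetics, tleaf) {
  stopifnot(inherits(kinetics, "aci_kinetics"))
  list(
    kc = kinetics$kc25 * arrhenius_factor(kinetics$ha[["kc"]], tleaf),
    ko = kinetics$ko25 * arrhenius_factor(kinetics$ha[["ko"]], tleaf),
    gamma_star = kinetics$gamma_star25 *
      arrhenius_factor(kinetics$ha[["gamma_star"]], tleaf),
    o = kinetics$o
  )
}

#' FvCB forward model
#'
#' @param ci Intercellular CO2 (µmol mol^-1), all > 0.
#' @param vcmax,j,rd Parameters at leaf temperature (µmol m^-2 s^-1).
#' @param kinetics From [bernacchi_kinetics()].
#' @param tleaf Leaf temperature (degrees C); kinetics are scaled to it.
#' @return A tibble: `ci`, `wc`, `wj`, `a` (net assimilation,
#'   `min(wc, wj) - rd`) and `limiting` (`"rubisco"` or `"rubp"`).
#' @examples
#' fvcb_forward(c(100, 300, 1000), vcmax = 100, j = 180, rd = 1.5)
#' @export
fvcb_forward <- function(ci, vcmax, j, rd,
                         kinetics = bernacchi_kinetics(), tleaf = 25) {
  if (any(ci <= 0)) abort("`ci` must be positive.")
  stopifnot(vcmax > 0, j > 0, rd >= 0)
  k <- kinetics_at(kinetics, tleaf)
  if (any(unlist(k) <= 0)) abort("Kinetic constants must be positive.")
  wc <- vcmax * (ci - k$gamma_star) / (ci + k$kc * (1 + k$o / k$ko))
  wj <- j * (ci - k$gamma_star) / (4 * ci + 8 * k$gamma_star)
  tibble::tibble(
    ci = as.numeric(ci),
    wc = wc,
    wj = wj,
    a = pmin(wc, wj) - rd,
    limiting = dplyr::if_else(wc <= wj, "rubisco", "rubp")
  )
}

aci_start_grid <- function(seed = NULL) {
  starts <- list(
    c(vcmax = 50, j = 100, rd = 1),
    c(vcmax = 100, j = 180, rd = 1.5),
    c(vcmax = 150, j = 250, rd = 2),
    c(vcmax = 220, j = 380, rd = 0.5),
    c(vcmax = 30, j = 60, rd = 3)
  )
  if (!is.null(seed)) {
    starts <- with_seed(seed, {
      purrr::map(starts, function(s) s * exp(rnorm(3, 0, 0.05)))
    })
  }
  starts
}

#' Fit the FvCB model to one A-Ci curve
#'
#' Minimises the residual sum of squares of [fvcb_forward()] over
#' `(Vcmax, J, Rd)` with a derivative-free Nelder-Mead simplex, started
#' from a coarse grid over Vcmax in `[20, 250]`, J in `[40, 400]` and Rd in
#' `[0.1, 5]` (optionally seed-jittered); positivity is enforced by
#' optimising on the log scale. Estimates are then normalised to 25
#' degrees C with the stored Arrhenius responses.
#'
#' @param curve Data frame with `ci`, `a` and optionally `tleaf`
#'   (degrees C, default 25); at least 5 distinct `ci` values.
#' @param kinetics From [bernacchi_kinetics()].
#' @param starts Number of multi-starts (up to 5).
#' @param seed Optional seed controlling start jitter.
#' @return An object of class `aci_fit`: `vcmax25`, `jmax25`, `rd25`
#'   (µmol m^-2 s^-1, normalised), the at-temperature estimates, `rss`,
#'   `converged`, per-point limiting process, and the input curve. Has
#'   [tidy()], [glance()] and [autoplot()] methods. Non-convergence after
#'   all starts is reported via `converged = FALSE`, not raised.
#' @examples
#' curve <- simulate_aci_curve(vcmax = 100, j = 180, rd = 1.5)
#' glance(fit_aci(curve))
#' @export
fit_aci <- function(curve, kinetics = bernacchi_kinetics(), starts = 5,
                    seed = NULL) {
  stopifnot(all(c("ci", "a") %in% names(curve)))
  if (length(unique(curve$ci)) < 5) {
    abort("At least 5 distinct Ci points are required to fit the FvCB model.")
  }
  tleaf <- if ("tleaf" %in% names(curve)) mean(curve$tleaf) else 25
  ci <- curve$ci
  obs <- curve$a
  k <- kinetics_at(kinetics, tleaf)
  objective <- function(logp) {
    p <- exp(logp)
    wc <- p[1] * (ci - k$gamma_star) / (ci + k$kc * (1 + k$o / k$ko))
    wj <- p[2] * (ci - k$gamma_star) / (4 * ci + 8 * k$gamma_star)
    sum((obs - (pmin(wc, wj) - p[3]))^2)
  }
  best <- NULL
  for (st in head(aci_start_grid(seed), starts)) {
    res <- tryCatch(
      optim(log(st), objective, method = "Nelder-Mead",
            control = list(maxit = 5000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(res) &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    return(structure(
      list(vcmax25 = NA_real_, jmax25 = NA_real_, rd25 = NA_real_,
           rss = NA_real_, converged = FALSE, tleaf = tleaf, curve = curve),
      class = "aci_fit"
    ))
  }
  p <- unname(exp(best$par))
  pred <- fvcb_forward(ci, p[1], p[2], p[3], kinetics, tleaf)
  structure(
    list(
      vcmax25 = normalize_25(p[1], tleaf, kinetics$ha[["vcmax"]]),
      jmax25 = normalize_25(p[2], tleaf, kinetics$ha[["jmax"]]),
      rd25 = normalize_25(p[3], tleaf, kinetics$ha[["rd"]]),
      vcmax_tleaf = p[1], j_tleaf = p[2], rd_tleaf = p[3],
      rss = best$value,
      converged = best$convergence == 0,
      limiting = pred$limiting,
      predicted = pred$a,
      tleaf = tleaf,
      curve = tibble::as_tibble(curve)
    ),
    class = "aci_fit"
  )
}

#' Fit many A-Ci curves from a long table
#'
#' @param curves Data frame with `curve_id`, `ci`, `a` and optionally
#'   `tleaf`.
#' @inheritParams fit_aci
#' @return A tibble, one row per curve: `curve_id`, `vcmax25`, `jmax25`,
#'   `rd25`, `rss`, `converged`.
#' @export
fit_aci_curves <- function(curves, kinetics = bernacchi_kinetics(),
                           starts = 5, seed = NULL) {
  curves |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_modify(function(g, key) {
      glance(fit_aci(g, kinetics = kinetics, starts = starts, seed = seed))
    }) |>
    dplyr::ungroup()
}

#' @method tidy aci_fit
#' @export
tidy.aci_fit <- function(x, ...) {
  tibble::tibble(
    term = c("vcmax25", "jmax25", "rd25"),
    estimate = c(x$vcmax25, x$jmax25, x$rd25)
  )
}

#' @method glance aci_fit
#' @export
glance.aci_fit <- function(x, ...) {
  tibble::tibble(
    vcmax25 = x$vcmax25, jmax25 = x$jmax25, rd25 = x$rd25,
    rss = x$rss, tleaf = x$tleaf, converged = x$converged
  )
}

#' @export
print.aci_fit <- function(x, ...) {
  cat("FvCB A-Ci fit (infinite mesophyll conductance)\n")
  if (!isTRUE(x$converged)) cat("  ** did not converge **\n")
  cat(sprintf("  Vcmax25 %.2f  Jmax25 %.2f  Rd25 %.3f  (RSS %.4g, Tleaf %.1f C)\n",
              x$vcmax25, x$jmax25, x$rd25, x$rss, x$tleaf))
  invisible(x)
}

#' Plot an A-Ci fit
#'
#' @param object An `aci_fit`.
#' @param ... Unused.
#' @return A ggplot of the measured points (coloured by the limiting
#'   process) with the fitted FvCB curve.
#' @method autoplot aci_fit
#' @export
autoplot.aci_fit <- function(object, ...) {
  if (!isTRUE(object$converged)) abort("Cannot plot a non-converged fit.")
  grid_ci <- seq(min(object$curve$ci), max(object$curve$ci), length.out = 200)
  smooth <- fvcb_forward(grid_ci, object$vcmax_tleaf, object$j_tleaf,
                         object$rd_tleaf, tleaf = object$tleaf)
  pts <- dplyr::mutate(object$curve, limiting = object$limiting)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$ci)) +
    ggplot2::geom_line(data = smooth, ggplot2::aes(y = .data$a)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$a, colour = .data$limiting)) +
    ggplot2::labs(
      x = expression(C[i] ~ (mu * mol ~ mol^-1)),
      y = expression(A ~ (mu * mol ~ m^-2 ~ s^-1)),
      colour = "Limitation"
    )
}
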