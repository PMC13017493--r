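#' Ground-truth curve parameters for simulated trait time courses
#'
#' Describes one of three canonical seasonal shapes for canopy traits
#' measured repeatedly through the season (days after planting, DAP):
#'
#' * `"logistic"` — sigmoidal rise to an asymptote (canopy coverage, early
#'   LAI): `asymptote / (1 + exp(-rate * (day - midpoint)))`.
#' * `"quadratic"` — concave rise-and-fall with an interior maximum (LAI,
#'   digital biomass): `asymptote - curvature * (day - peak_day)^2`.
#' * `"rise-plateau-decline"` — logistic rise, plateau near the asymptote,
#'   then linear senescent decline starting at `decline_onset_day` (NDVI).
#'
#' @param family One of `"logistic"`, `"quadratic"`,
#'   `"rise-plateau-decline"`.
#' @param asymptote Plateau or peak value (trait units); must be positive.
#' @param midpoint Day of the sigmoid midpoint (logistic families).
#' @param rate Logistic growth rate (per day).
#' @param peak_day Day of the quadratic vertex.
#' @param curvature Quadratic curvature (trait units per day^2), positive.
#' @param decline_onset_day Day the senescent decline starts.
#' @param decline_rate Decline slope (trait units per day), positive.
#' @param noise_sd Measurement noise SD (trait units).
#' @return An object of class `curve_params`.
#' @export
curve_params <- function(family = c("logistic", "quadratic", "rise-plateau-decline"),
                         asymptote = 1,
                         midpoint = 45,
                         rate = 0.25,
                         peak_day = 70,
                         curvature = 0.004,
                         decline_onset_day = 80,
                         decline_rate = 0.03,
                         noise_sd = 0) {
  family <- match.arg(family)
  stopifnot(asymptote > 0, curvature > 0, decline_rate > 0, noise_sd >= 0)
  structure(
    list(
      family = family, asymptote = asymptote, midpoint = midpoint,
      rate = rate, peak_day = peak_day, curvature = curvature,
      decline_onset_day = decline_onset_day, decline_rate = decline_rate,
      noise_sd = noise_sd
    ),
    class = "curve_params"
  )
}

#' Evaluate a ground-truth curve (noise-free)
#'
#' @param params A [curve_params()].
#' @param days Numeric vector of days after planting.
#' @return Numeric vector of trait values.
#' @export
eval_curve <- function(params, days) {
  stopifnot(inherits(params, "curve_params"))
  logi <- params$asymptote / (1 + exp(-params$rate * (days - params$midpoint)))
  switch(params$family,
    "logistic" = logi,
    "quadratic" = params$asymptote - params$curvature * (days - params$peak_day)^2,
    "rise-plateau-decline" =
      logi - params$decline_rate * pmax(0, days - params$decline_onset_day)
  )
}

# True temporal parameters implied by a curve over a sampling window.
curve_truth <- function(params, window) {
  peak_day <- switch(params$family,
    "logistic" = window[2],
    "quadratic" = params$peak_day,
    "rise-plateau-decline" = params$decline_onset_day
  )
  tibble::tibble(
    family = params$family,
    peak_day = peak_day,
    peak_value = eval_curve(params, peak_day),
    midpoint_day = if (params$family == "quadratic") NA_real_ else params$midpoint,
    decline_onset_day = if (params$family == "rise-plateau-decline") {
      params$decline_onset_day
    } else {
      NA_real_
    }
  )
}

#' Simulate per-plot trait time courses over a layout
#'
#' Each plot receives the ground-truth curve evaluated at `sampling_days`
#' plus independent Gaussian noise. The true temporal parameters (peak day
#' and value, sigmoid midpoint, decline onset) are returned alongside so
#' extraction accuracy can be measured.
#'
#' @param layout A layout from [generate_layout()], or any data frame with a
#'   `plot_id` column.
#' @param params A [curve_params()].
#' @param sampling_days Strictly increasing measurement days.
#' @param trait Trait label.
#' @param seed Integer seed.
#' @return A list with `series` (tibble: `plot_id`, `trait`, `day`, `value`)
#'   and `truth` (one row per plot of true temporal parameters).
#' @export
simulate_timecourse <- function(layout, params, sampling_days,
                                trait = "LAI", seed = NULL) {
  stopifnot(inherits(params, "curve_params"))
  if (length(sampling_days) == 0) abort("`sampling_days` must be non-empty.")
  if (any(diff(sampling_days) <= 0)) {
    abort("`sampling_days` must be strictly increasing.")
  }
  ids <- unique(layout$plot_id)
  base <- eval_curve(params, sampling_days)
  with_seed(seed, {
    series <- tidyr::expand_grid(plot_id = ids, day = sampling_days) |>
      dplyr::mutate(
        trait = trait,
        value = rep(base, times = length(ids)) +
          rnorm(dplyr::n(), 0, params$noise_sd)
      ) |>
      dplyr::select("plot_id", "trait", "day", "value")
    truth <- tidyr::expand_grid(
      plot_id = ids,
      curve_truth(params, range(sampling_days))
    )
    list(series = series, truth = truth)
  })
}
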