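#' Simulate a 4-channel plot image with known canopy coverage
#'
#' Builds an `(H, W, 4)` array (channels R, G, B, NIR, values in `[0, 1]`)
#' containing exactly `round(coverage_fraction * H * W)` vegetation pixels
#' at uniformly random positions; the rest are soil. Vegetation pixels are
#' green-dominant with high NIR (positive Excess Green, high NDVI), soil
#' pixels the opposite, so segmentation methods can be scored against the
#' returned truth mask. Optional Gaussian channel noise emulates sensor and
#' illumination variation.
#'
#' @param coverage_fraction Target vegetation fraction in `[0, 1]`.
#' @param shape Integer `c(H, W)` image shape.
#' @param noise_sd Per-channel Gaussian noise SD (0 = noise-free two-class
#'   image); channels are clipped to `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `image` (numeric `(H, W, 4)` array) and `mask`
#'   (logical `H x W` truth matrix, `TRUE` = vegetation).
#' @export
simulate_plot_image <- function(coverage_fraction, shape = c(100L, 100L),
                                noise_sd = 0, seed = NULL) {
  stopifnot(length(shape) == 2L)
  if (any(shape < 1)) abort("`shape` must be positive.")
  if (coverage_fraction < 0 || coverage_fraction > 1) {
    abort("`coverage_fraction` must be in [0, 1].")
  }
  h <- as.integer(shape[1])
  w <- as.integer(shape[2])
  npix <- h * w
  n_veg <- round(coverage_fraction * npix)

  # class-conditional channel means (R, G, B, NIR)
  veg <- c(0.15, 0.45, 0.12, 0.70)
  soil <- c(0.40, 0.32, 0.30, 0.25)

  with_seed(seed, {
    mask <- matrix(FALSE, h, w)
    if (n_veg > 0) mask[sample.int(npix, n_veg)] <- TRUE
    img <- array(0, dim = c(h, w, 4L))
    for (k in 1:4) {
      ch <- ifelse(mask, veg[k], soil[k])
      if (noise_sd > 0) ch <- ch + rnorm(npix, 0, noise_sd)
      img[, , k] <- pmin(1, pmax(0, ch))
    }
    list(image = img, mask = mask)
  })
}

#' Simulate a box-shaped canopy point cloud
#'
#' Draws points uniformly inside an axis-aligned box of the given footprint
#' and height, emulating the point cloud of a closed rectangular canopy.
#' The point count is `round(points_per_m3 * volume)`.
#'
#' @param footprint_m Numeric `c(length_x, length_y)` in metres.
#' @param height_m Canopy height in metres (0 gives an empty cloud).
#' @param points_per_m3 Point density; must be positive.
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y`, `z` (metres) and attribute
#'   `area_m2` holding the plot footprint area.
#' @export
simulate_point_cloud <- function(footprint_m, height_m, points_per_m3,
                                 seed = NULL) {
  stopifnot(length(footprint_m) == 2L)
  if (any(footprint_m <= 0) || height_m < 0) {
    abort("Footprint dimensions must be positive and height non-negative.")
  }
  if (points_per_m3 <= 0) abort("`points_per_m3` must be positive.")
  volume <- prod(footprint_m) * height_m
  n <- round(points_per_m3 * volume)
  with_seed(seed, {
    cloud <- tibble::tibble(
      x = runif(n, 0, footprint_m[1]),
      y = runif(n, 0, footprint_m[2]),
      z = runif(n, 0, height_m)
    )
    attr(cloud, "area_m2") <- prod(footprint_m)
    cloud
  })
}

#' Simulate an A-Ci gas-exchange curve from the FvCB forward model
#'
#' Evaluates the C3 FvCB model at the given intercellular CO2 setpoints and
#' adds Gaussian measurement noise. The default setpoints follow a common
#' 14-step survey protocol (down from 400 ppm, recovery at 400, then up to
#' 1800 ppm); repeated 400-ppm points are retained as independent
#' observations.
#'
#' @param vcmax,j,rd FvCB parameters at leaf temperature
#'   (µmol m^-2 s^-1): maximum carboxylation rate, electron transport rate,
#'   day respiration.
#' @param tleaf Leaf temperature (degrees C).
#' @param kinetics Rubisco kinetics from [bernacchi_kinetics()].
#' @param ci_setpoints Intercellular CO2 setpoints (µmol mol^-1), all > 0.
#' @param noise_sd Assimilation noise SD (µmol m^-2 s^-1).
#' @param curve_id Identifier stored in the output.
#' @param seed Integer seed.
#' @return A tibble with `curve_id`, `ci`, `a`, `tleaf`; the generating
#'   parameters are attached as attribute `truth`.
#' @export
simulate_aci_curve <- function(vcmax, j, rd,
                               tleaf = 25,
                               kinetics = bernacchi_kinetics(),
                               ci_setpoints = aci_setpoints(),
                               noise_sd = 0,
                               curve_id = "leaf_1",
                               seed = NULL) {
  if (any(ci_setpoints <= 0)) abort("All `ci_setpoints` must be positive.")
  stopifnot(vcmax > 0, j > 0, rd >= 0, noise_sd >= 0)
  pred <- fvcb_forward(ci_setpoints, vcmax = vcmax, j = j, rd = rd,
                       kinetics = kinetics, tleaf = tleaf)
  with_seed(seed, {
    curve <- tibble::tibble(
      curve_id = curve_id,
      ci = as.numeric(ci_setpoints),
      a = pred$a + rnorm(length(ci_setpoints), 0, noise_sd),
      tleaf = tleaf
    )
    attr(curve, "truth") <- list(vcmax = vcmax, j = j, rd = rd)
    curve
  })
}

#' Standard 14-step A-Ci survey setpoints
#'
#' @return Numeric vector of 14 CO2 setpoints (µmol mol^-1).
#' @export
aci_setpoints <- function() {
  c(400, 300, 200, 100, 75, 50, 25, 400, 400, 600, 800, 1000, 1200, 1800)
}
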