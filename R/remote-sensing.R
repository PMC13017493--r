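#' @name remote_sensing
#' @title Canopy coverage, NDVI and voxel-grid digital biomass
#'
#' @description
#' Plot-level canopy indices from 4-channel (R, G, B, NIR) imagery and
#' LiDAR-style point clouds: the Excess Green index `2G - (R + B)` with
#' Otsu or fixed thresholding for vegetation/soil segmentation, percent
#' canopy coverage inside a plot boundary, NDVI `(NIR - R)/(NIR + R)` with
#' zonal statistics, and digital biomass as voxel-grid canopy volume per
#' unit ground area.
NULL

check_image <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 4L) {
    abort("`image` must be an (H, W, 4) array with channels R, G, B, NIR.")
  }
  invisible(image)
}

#' Excess Green vegetation index
#'
#' @param image `(H, W, 4)` array, channels R, G, B, NIR in `[0, 1]`.
#' @return `H x W` matrix of `2G - (R + B)` values.
#' @export
excess_green <- function(image) {
  check_image(image)
  out <- 2 * image[, , 2, drop = TRUE] -
    (image[, , 1, drop = TRUE] + image[, , 3, drop = TRUE])
  matrix(out, dim(image)[1], dim(image)[2])
}

# Exact Otsu threshold: exhaustively minimises the within-class variance
# over the midpoints between consecutive distinct values.
otsu_threshold <- function(x) {
  v <- sort(unique(as.numeric(x)))
  if (length(v) < 2) return(NA_real_)
  cand <- (head(v, -1) + tail(v, -1)) / 2
  x <- as.numeric(x)
  wcv <- vapply(cand, function(t) {
    lo <- x[x <= t]
    hi <- x[x > t]
    length(lo) * var1(lo) + length(hi) * var1(hi)
  }, numeric(1))
  cand[which.min(wcv)]
}

var1 <- function(x) if (length(x) < 2) 0 else var(x) * (length(x) - 1) / length(x)

#' Segment vegetation from an index image
#'
#' @param index_array Numeric matrix (e.g. from [excess_green()]).
#' @param method `"otsu"` (default; exact between-class-variance optimal
#'   threshold on the index values) or `"fixed"`.
#' @param threshold Threshold used when `method = "fixed"`.
#' @return Logical mask, `TRUE` where `index > threshold`. A constant
#'   index under Otsu falls back to a fixed threshold of 0 with a warning.
#' @export
segment_vegetation <- function(index_array, method = c("otsu", "fixed"),
                               threshold = 0) {
  method <- match.arg(method)
  if (any(!is.finite(index_array))) abort("`index_array` must be finite.")
  t <- if (method == "otsu") {
    ot <- otsu_threshold(index_array)
    if (is.na(ot)) {
      warn("Index image is constant; falling back to a fixed threshold of 0.")
      0
    } else {
      ot
    }
  } else {
    threshold
  }
  index_array > t
}

check_boundary <- function(boundary, dims) {
  stopifnot(length(boundary) == 4L)
  r0 <- boundary[1]; r1 <- boundary[2]; c0 <- boundary[3]; c1 <- boundary[4]
  if (r0 < 0 || c0 < 0 || r1 > dims[1] || c1 > dims[2] || r1 <= r0 || c1 <= c0) {
    abort("`boundary` must be a non-empty half-open rectangle [r0, r1) x [c0, c1) inside the image.")
  }
  list(rows = (r0 + 1):r1, cols = (c0 + 1):c1)
}

#' Percent canopy coverage inside a plot boundary
#'
#' @param mask Logical vegetation mask (from [segment_vegetation()]).
#' @param boundary Optional `c(r0, r1, c0, c1)` half-open pixel rectangle
#'   (0-based); default is the whole mask.
#' @return Percentage of vegetation pixels inside the boundary, in
#'   `[0, 100]`.
#' @export
canopy_coverage <- function(mask, boundary = NULL) {
  if (is.null(boundary)) {
    return(100 * mean(mask))
  }
  z <- check_boundary(boundary, dim(mask))
  100 * mean(mask[z$rows, z$cols])
}

#' NDVI index image
#'
#' @inheritParams excess_green
#' @return `H x W` matrix of `(NIR - R)/(NIR + R)`; pixels with
#'   `NIR + R = 0` are `NA`.
#' @export
ndvi <- function(image) {
  check_image(image)
  nir <- image[, , 4, drop = TRUE]
  r <- image[, , 1, drop = TRUE]
  denom <- nir + r
  out <- (nir - r) / denom
  out[denom == 0] <- NA_real_
  matrix(out, dim(image)[1], dim(image)[2])
}

#' Zonal NDVI statistic for a plot
#'
#' @inheritParams excess_green
#' @param boundary `c(r0, r1, c0, c1)` half-open pixel rectangle (0-based);
#'   `NULL` for the whole image.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return Scalar zonal NDVI.
#' @export
zonal_ndvi <- function(image, boundary = NULL, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  nd <- ndvi(image)
  vals <- if (is.null(boundary)) {
    as.numeric(nd)
  } else {
    z <- check_boundary(boundary, dim(nd))
    as.numeric(nd[z$rows, z$cols])
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) abort("Boundary contains no valid NDVI pixels.")
  if (statistic == "mean") mean(vals) else median(vals)
}

#' Digital biomass from a voxelised point cloud
#'
#' Canopy volume is counted as (number of occupied voxels) x voxel_size^3,
#' with the voxel grid anchored at the cloud's minimum corner and a voxel
#' occupied when at least one point falls inside it; digital biomass is
#' that volume divided by the plot footprint area.
#'
#' @param cloud Data frame with `x`, `y`, `z` (metres), e.g. from
#'   [simulate_point_cloud()] or [read_xyz()].
#' @param voxel_size_m Voxel edge length in metres (> 0).
#' @param area_m2 Plot footprint area; defaults to the cloud's `area_m2`
#'   attribute.
#' @return Digital biomass in m^3 per m^2 (0 for an empty cloud).
#' @export
digital_biomass <- function(cloud, voxel_size_m, area_m2 = NULL) {
  if (voxel_size_m <= 0) abort("`voxel_size_m` must be positive.")
  area_m2 <- area_m2 %||% attr(cloud, "area_m2")
  if (is.null(area_m2) || area_m2 <= 0) {
    abort("A positive plot `area_m2` is required (argument or cloud attribute).")
  }
  if (nrow(cloud) == 0) return(0)
  p <- as.matrix(cloud[, c("x", "y", "z")])
  if (any(!is.finite(p))) abort("Point cloud contains non-finite coordinates.")
  idx <- floor(sweep(p, 2, apply(p, 2, min)) / voxel_size_m)
  n_occ <- nrow(unique(idx))
  n_occ * voxel_size_m^3 / area_m2
}

#' Canopy indices for a set of plot images
#'
#' Convenience wrapper: segments each image with Excess Green + Otsu and
#' returns coverage and mean NDVI per plot.
#'
#' @param images Named list of `(H, W, 4)` arrays (names = plot ids).
#' @param method,threshold Passed to [segment_vegetation()].
#' @return Tibble: `plot_id`, `coverage_pct`, `ndvi_mean`.
#' @export
plot_indices <- function(images, method = "otsu", threshold = 0) {
  purrr::imap_dfr(images, function(img, id) {
    mask <- segment_vegetation(excess_green(img), method = method,
                               threshold = threshold)
    tibble::tibble(
      plot_id = id,
      coverage_pct = canopy_coverage(mask),
      ndvi_mean = zonal_ndvi(img)
    )
  })
}

#' Read / write XYZ point-cloud text files
#'
#' Plain whitespace-separated `x y z` text, one point per line.
#'
#' @param path File path.
#' @param cloud Data frame with `x`, `y`, `z`.
#' @return `read_xyz()` returns a tibble with `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  m <- as.matrix(read.table(path, col.names = c("x", "y", "z")))
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}

#' @rdname read_xyz
#' @export
write_xyz <- function(cloud, path) {
  utils::write.table(cloud[, c("x", "y", "z")], path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a 4-channel plot image as TIFF
#'
#' Channels R, G, B, NIR as a 4-sample float TIFF (requires the `tiff`
#' package).
#'
#' @param path File path.
#' @param image `(H, W, 4)` array in `[0, 1]`.
#' @return `read_plot_image()` returns the `(H, W, 4)` array.
#' @export
read_plot_image <- function(path) {
  rlang::check_installed("tiff")
  img <- tiff::readTIFF(path)
  check_image(img)
  img
}

#' @rdname read_plot_image
#' @export
write_plot_image <- function(image, path) {
  rlang::check_installed("tiff")
  check_image(image)
  tiff::writeTIFF(image, path, bits.per.sample = 32L)
  invisible(path)
}
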