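#' Generate a Type-II Modified Augmented Design field layout
#'
#' Lays out `n_blocks` rectangular blocks of unreplicated test plots, each
#' with a replicated primary check (`check1`) at the block centre and each
#' secondary check (`check2a`, `check2b`, ...) placed exactly once per block
#' at a uniformly random non-central cell. Blocks tile the field row-wise on
#' a block grid with `field_cols` columns; every plot carries both its
#' plot-grid address (`row`, `col`) and its whole-plot address
#' (`block_row`, `block_col`), the granularity at which the design-structure
#' spatial adjustment estimates row and column effects.
#'
#' @param n_blocks Number of blocks (whole plots), at least 1.
#' @param block_shape Integer vector `c(rows, cols)` of the within-block plot
#'   grid. Both must be odd so the block has a unique central cell
#'   (default `c(5, 5)`, i.e. 25 plots per block).
#' @param field_cols Number of block columns in the field; blocks fill
#'   row-wise. Default `ceiling(sqrt(n_blocks))`.
#' @param n_secondary Number of secondary check genotypes (default 2).
#' @param location,spacing Stratum labels attached to every plot.
#' @param seed Integer seed controlling secondary-check placement and the
#'   leaf-shape assignment of test genotypes.
#'
#' @return A tibble with one row per plot: `plot_id`, `block`, `block_row`,
#'   `block_col`, `row`, `col` (0-based plot-grid indices over the full
#'   field), `role` (`test`, `check1`, `check2a`, `check2b`, ...),
#'   `genotype`, `leaf_shape`, `location`, `spacing`.
#' @examples
#' layout <- generate_layout(n_blocks = 9, seed = 1)
#' dplyr::count(layout, role)
#' @export
generate_layout <- function(n_blocks,
                            block_shape = c(5L, 5L),
                            field_cols = NULL,
                            n_secondary = 2L,
                            location = "SF",
                            spacing = "76cm",
                            seed = NULL) {
  stopifnot(length(n_blocks) == 1L, n_blocks >= 1, length(block_shape) == 2L)
  block_shape <- as.integer(block_shape)
  if (any(block_shape < 1) || any(block_shape %% 2L == 0L)) {
    abort("`block_shape` must be odd x odd so the block has a unique central cell.")
  }
  n_blocks <- as.integer(n_blocks)
  field_cols <- as.integer(field_cols %||% ceiling(sqrt(n_blocks)))
  stopifnot(field_cols >= 1)
  br <- block_shape[1]
  bc <- block_shape[2]
  centre <- c((br - 1L) %/% 2L, (bc - 1L) %/% 2L)

  with_seed(seed, {
    blocks <- purrr::map(seq_len(n_blocks), function(b) {
      block_row <- (b - 1L) %/% field_cols
      block_col <- (b - 1L) %% field_cols
      cells <- tidyr::expand_grid(r = 0:(br - 1L), c = 0:(bc - 1L))
      role <- rep("test", nrow(cells))
      is_centre <- cells$r == centre[1] & cells$c == centre[2]
      role[is_centre] <- "check1"
      open <- which(!is_centre)
      picked <- sample(open, n_secondary)
      role[picked] <- paste0("check2", letters[seq_len(n_secondary)])
      tibble::tibble(
        block = b,
        block_row = block_row,
        block_col = block_col,
        row = block_row * br + cells$r,
        col = block_col * bc + cells$c,
        role = role
      )
    })
    layout <- dplyr::bind_rows(blocks)

    n_test <- sum(layout$role == "test")
    test_geno <- sprintf("NIL_%03d", seq_len(n_test))
    test_shape <- sample(rep_len(c("broad", "narrow"), n_test))
    layout <- layout |>
      dplyr::mutate(
        genotype = dplyr::case_when(
          role == "test" ~ NA_character_,
          role == "check1" ~ "P_check1",
          TRUE ~ paste0("P_", role)
        ),
        leaf_shape = dplyr::if_else(role == "check1", "broad", "narrow")
      )
    layout$genotype[layout$role == "test"] <- test_geno
    layout$leaf_shape[layout$role == "test"] <- test_shape
    layout |>
      dplyr::mutate(
        plot_id = sprintf("B%02d_%02d_%02d", .data$block, .data$row, .data$col),
        location = location,
        spacing = spacing
      ) |>
      dplyr::select(
        "plot_id", "block", "block_row", "block_col", "row", "col",
        "role", "genotype", "leaf_shape", "location", "spacing"
      )
  })
}

#' Ground truth for a simulated MAD trial
#'
#' Bundles the additive components of the simulated trait model
#' `value = grand_mean + genotype_effect + row_effect + col_effect
#' (+ trend) + noise`. Row and column effects act at the whole-plot (block
#' grid) granularity — the form the design-structure adjustment models — and
#' are re-centred to sum to zero. An optional smooth plot-level trend
#' function exercises robustness to spatial structure the additive model
#' does not capture.
#'
#' @param genotype_effects Named numeric vector mapping every genotype in the
#'   layout to its true effect (deviation from `grand_mean`).
#' @param row_effects,col_effects Numeric vectors of block-row / block-column
#'   effects (recycled-length checked downstream); centred to mean zero.
#' @param grand_mean Overall trait mean.
#' @param noise_sd Residual standard deviation.
#' @param trend Optional `function(row, col)` evaluated at plot-grid indices
#'   and added to every plot.
#' @return An object of class `trial_truth`.
#' @export
trial_truth <- function(genotype_effects,
                        row_effects = 0,
                        col_effects = 0,
                        grand_mean = 0,
                        noise_sd = 0,
                        trend = NULL) {
  stopifnot(is.numeric(genotype_effects), !is.null(names(genotype_effects)))
  structure(
    list(
      genotype_effects = genotype_effects,
      row_effects = row_effects - mean(row_effects),
      col_effects = col_effects - mean(col_effects),
      grand_mean = grand_mean,
      noise_sd = noise_sd,
      trend = trend
    ),
    class = "trial_truth"
  )
}

#' Draw a random ground truth for a layout
#'
#' @param layout A layout from [generate_layout()].
#' @param grand_mean Trait mean (trait units).
#' @param genotype_sd SD of genotype effects across test lines.
#' @param gradient_sd SD of the block-row and block-column effects.
#' @param noise_sd Residual SD.
#' @param seed Integer seed.
#' @return A `trial_truth`.
#' @export
random_trial_truth <- function(layout, grand_mean = 0, genotype_sd = 1,
                               gradient_sd = 1, noise_sd = 0.5, seed = NULL) {
  with_seed(seed, {
    genos <- unique(layout$genotype)
    g <- rnorm(length(genos), 0, genotype_sd)
    names(g) <- genos
    nr <- max(layout$block_row) + 1L
    nc <- max(layout$block_col) + 1L
    trial_truth(
      genotype_effects = g,
      row_effects = rnorm(nr, 0, gradient_sd),
      col_effects = rnorm(nc, 0, gradient_sd),
      grand_mean = grand_mean,
      noise_sd = noise_sd
    )
  })
}

#' Simulate one trait over a MAD layout
#'
#' Generates plot values under the additive model held by `truth` and joins
#' them to the layout, producing the plot table that the spatial-adjustment
#' functions consume.
#'
#' @param layout A layout from [generate_layout()].
#' @param truth A [trial_truth()].
#' @param trait Trait label stored in the output.
#' @param seed Integer seed for the residual noise.
#' @return The layout tibble with `trait` and `value` columns appended.
#' @export
simulate_trial <- function(layout, truth, trait = "trait", seed = NULL) {
  stopifnot(inherits(truth, "trial_truth"))
  missing <- setdiff(unique(layout$genotype), names(truth$genotype_effects))
  if (length(missing) > 0) {
    abort(paste0(
      "No genotype effect supplied for: ",
      paste(missing, collapse = ", ")
    ))
  }
  re <- truth$row_effects
  ce <- truth$col_effects
  nr <- max(layout$block_row) + 1L
  nc <- max(layout$block_col) + 1L
  if (length(re) == 1L) re <- rep(re, nr)
  if (length(ce) == 1L) ce <- rep(ce, nc)
  stopifnot(length(re) >= nr, length(ce) >= nc)
  with_seed(seed, {
    val <- truth$grand_mean +
      unname(truth$genotype_effects[layout$genotype]) +
      re[layout$block_row + 1L] +
      ce[layout$block_col + 1L]
    if (!is.null(truth$trend)) {
      val <- val + truth$trend(layout$row, layout$col)
    }
    if (truth$noise_sd > 0) {
      val <- val + rnorm(nrow(layout), 0, truth$noise_sd)
    }
    layout |> dplyr::mutate(trait = trait, value = val)
  })
}

#' Simulate leaf-ratio measurements from a bimodal genotype structure
#'
#' Near-isogenic populations segregating for a narrow-leaf allele show a
#' two-component leaf-ratio (leaflet length / maximum width) distribution;
#' the defaults place the broad and narrow component means at 1.3 and 2.4.
#'
#' @param n Number of measurements.
#' @param means Component means, broad then narrow.
#' @param sds Component SDs.
#' @param weights Mixing weights (normalised internally).
#' @param seed Integer seed.
#' @return A tibble with `leaf_shape` and `leaf_ratio`.
#' @export
simulate_leaf_ratio <- function(n, means = c(1.3, 2.4), sds = c(0.15, 0.15),
                                weights = c(0.5, 0.5), seed = NULL) {
  stopifnot(length(means) == 2L, length(sds) == 2L, all(sds > 0))
  weights <- weights / sum(weights)
  with_seed(seed, {
    comp <- sample(1:2, n, replace = TRUE, prob = weights)
    tibble::tibble(
      leaf_shape = c("broad", "narrow")[comp],
      leaf_ratio = rnorm(n, means[comp], sds[comp])
    )
  })
}
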