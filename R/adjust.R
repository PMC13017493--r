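#' @name mad_adjust
#' @title Check-plot spatial adjustment for Type-II Modified Augmented Designs
#'
#' @description
#' In a Type-II MAD the test genotypes are unreplicated; spatial trend is
#' estimated from a replicated primary check at every block centre and two
#' secondary checks placed once per block. Two corrections are implemented:
#'
#' * **Method I** (adjustment by design structure): model the primary-check
#'   values as `Y = mu + R_i + C_j + e` over the whole-plot (block-grid)
#'   rows and columns and correct every plot by
#'   `Y_adj = Y - R_i - C_j + 2 * mu`, where `R_i`/`C_j` are the
#'   primary-check means of the plot's block-row/block-column and `mu` the
#'   primary-check grand mean.
#' * **Method III** (adjustment by regression): regress the per-block
#'   primary-check value on the per-block secondary-check average across
#'   blocks, then correct every plot by
#'   `Y_adj = Y - beta * (check1_block - check2_ref) + alpha`.
#'
#' Whether either correction is worth applying is decided by the relative
#' efficiency `RE = 100 * IWP_original / IWP_adjusted`, where the
#' intra-whole-plot (IWP) error pools the squared deviations of each
#' secondary check around its own across-block mean.
NULL

check_plot_table <- function(table, need_secondary = FALSE) {
  need <- c("block", "block_row", "block_col", "role", "value")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    abort(paste0("Plot table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!any(table$role == "check1")) {
    abort("Plot table contains no primary-check (check1) plots.")
  }
  if (need_secondary && !any(startsWith(table$role, "check2"))) {
    abort("Plot table contains no secondary-check (check2*) plots.")
  }
  invisible(table)
}

#' Method I: adjustment by design structure
#'
#' @param table A plot table (one trait): columns `block`, `block_row`,
#'   `block_col`, `role`, `value` (plus any others, carried through).
#' @return The table with a `value_adj` column appended; the fit (class
#'   `mad_method1`: block-row means, block-column means, grand mean of the
#'   primary check) is attached as attribute `fit` and has [tidy()] /
#'   [glance()] methods. Check plots are adjusted too, for diagnostics.
#' @details Block-rows or block-columns that contain no primary check fall
#'   back to `R_i = mu` (zero estimated deviation).
#' @examples
#' tab <- simulate_trial(generate_layout(9, seed = 1),
#'                       random_trial_truth(generate_layout(9, seed = 1), seed = 2))
#' adj <- method1_adjust(tab)
#' glance(attr(adj, "fit"))
#' @export
method1_adjust <- function(table) {
  check_plot_table(table)
  checks <- dplyr::filter(table, .data$role == "check1")
  mu <- mean(checks$value)
  row_means <- checks |>
    dplyr::summarise(r = mean(.data$value), .by = "block_row")
  col_means <- checks |>
    dplyr::summarise(c = mean(.data$value), .by = "block_col")
  out <- table |>
    dplyr::left_join(row_means, by = "block_row") |>
    dplyr::left_join(col_means, by = "block_col") |>
    dplyr::mutate(
      r = dplyr::coalesce(.data$r, mu),
      c = dplyr::coalesce(.data$c, mu),
      value_adj = .data$value - .data$r - .data$c + 2 * mu
    ) |>
    dplyr::select(-"r", -"c")
  fit <- structure(
    list(grand_mean = mu, row_means = row_means, col_means = col_means),
    class = "mad_method1"
  )
  attr(out, "fit") <- fit
  out
}

#' Method III: adjustment by regression on the checks
#'
#' @inheritParams method1_adjust
#' @param check2_reference `"grand"` (default) uses the grand mean of the
#'   per-block secondary-check averages as the reference level in the
#'   correction; `"block"` uses each block's own secondary-check average.
#' @return The table with `value_adj` appended; the fit (class
#'   `mad_method3`: `beta`, `alpha`, the per-block check summaries and the
#'   reference) is attached as attribute `fit`.
#' @details Requires at least 3 blocks with both a primary-check value and
#'   a secondary-check average. If the per-block secondary-check averages
#'   have zero variance the regression slope is undefined and an error of
#'   class `canopytrial_method3_unavailable` is signalled; the selection
#'   rule then falls back to Method I only.
#' @export
method3_adjust <- function(table, check2_reference = c("grand", "block")) {
  check2_reference <- match.arg(check2_reference)
  check_plot_table(table, need_secondary = TRUE)
  per_block <- table |>
    dplyr::filter(startsWith(.data$role, "check")) |>
    dplyr::summarise(
      check1 = mean(.data$value[.data$role == "check1"]),
      check2_avg = mean(.data$value[startsWith(.data$role, "check2")]),
      .by = "block"
    )
  per_block <- dplyr::filter(per_block, is.finite(.data$check1),
                             is.finite(.data$check2_avg))
  if (nrow(per_block) < 3) {
    abort("Method III needs >= 3 blocks with primary and secondary checks.",
          class = "canopytrial_method3_unavailable")
  }
  if (var(per_block$check2_avg) < .Machine$double.eps) {
    abort("Secondary-check averages are constant across blocks; regression slope undefined.",
          class = "canopytrial_method3_unavailable")
  }
  ols <- lm(check1 ~ check2_avg, data = per_block)
  beta <- unname(coef(ols)[2])
  alpha <- unname(coef(ols)[1])
  ref <- if (check2_reference == "grand") {
    mean(per_block$check2_avg)
  } else {
    NA_real_ # per-block: looked up below
  }
  out <- table |>
    dplyr::left_join(per_block, by = "block") |>
    dplyr::mutate(
      .ref = if (check2_reference == "grand") ref else .data$check2_avg,
      value_adj = .data$value - beta * (.data$check1 - .data$.ref) + alpha
    ) |>
    dplyr::select(-"check1", -"check2_avg", -".ref")
  fit <- structure(
    list(beta = beta, alpha = alpha, per_block = per_block,
         check2_reference = check2_reference,
         reference_value = if (check2_reference == "grand") ref else NULL),
    class = "mad_method3"
  )
  attr(out, "fit") <- fit
  out
}

#' Intra-whole-plot error from the secondary checks
#'
#' Pools, across blocks, each secondary check's sum of squared deviations
#' from its own mean: `IWP = (SS_1 + SS_2) / (2 * (n_1 + n_2 - 2))` with
#' `n_k` the number of blocks carrying check `k`.
#'
#' @param table A plot table with secondary-check plots.
#' @param value_col Column to compute the error from (`"value"` for the
#'   raw error, `"value_adj"` for the adjusted error).
#' @return Non-negative scalar (trait units squared).
#' @export
iwp_error <- function(table, value_col = "value") {
  check_plot_table(table, need_secondary = TRUE)
  checks <- table |>
    dplyr::filter(startsWith(.data$role, "check2")) |>
    dplyr::summarise(x = mean(.data[[value_col]]),
                     .by = c("role", "block"))
  per_check <- checks |>
    dplyr::summarise(ss = sum((.data$x - mean(.data$x))^2),
                     n = dplyr::n(), .by = "role")
  k <- nrow(per_check)
  df <- sum(per_check$n) - k
  if (df <= 0 || sum(per_check$n) <= 2) {
    abort("Intra-whole-plot error undefined: secondary checks observed in too few blocks (n1 + n2 <= 2).")
  }
  sum(per_check$ss) / (k * df)
}

#' Relative efficiency of a spatial adjustment
#'
#' @param iwp_original Intra-whole-plot error before adjustment (>= 0).
#' @param iwp_adjusted Intra-whole-plot error after adjustment (>= 0).
#' @return `100 * iwp_original / iwp_adjusted`; values >= 100 mean the
#'   adjustment reduced the error. Both zero returns 100 (no information);
#'   a zero adjusted error with a positive original error returns `Inf`
#'   with a warning.
#' @export
relative_efficiency <- function(iwp_original, iwp_adjusted) {
  stopifnot(iwp_original >= 0, iwp_adjusted >= 0)
  if (iwp_adjusted == 0) {
    if (iwp_original == 0) return(100)
    warn("Adjusted intra-whole-plot error is zero; relative efficiency is infinite.")
    return(Inf)
  }
  100 * iwp_original / iwp_adjusted
}

#' The three-rule relative-efficiency criterion
#'
#' Encodes the published decision rule for whether (and which) spatial
#' adjustment to apply: if both REs are below 100 no adjustment is applied
#' (the precision gain is insufficient); if exactly one RE is at least 100
#' that method is chosen; if both are, the method with the higher RE is
#' selected. An exact tie at RE >= 100 goes to Method I, which uses the
#' design structure. An `NA` RE (method unavailable) removes that method
#' from consideration.
#'
#' @param re_method1,re_method3 Relative efficiencies on the 100 scale
#'   (`NA` = method unavailable).
#' @return `"none"`, `"method1"` or `"method3"`.
#' @examples
#' choose_adjustment_method(95, 80)   # none
#' choose_adjustment_method(90, 130)  # method3
#' choose_adjustment_method(140, 120) # method1
#' @export
choose_adjustment_method <- function(re_method1, re_method3) {
  re <- c(method1 = unname(re_method1), method3 = unname(re_method3))
  eligible <- re[!is.na(re) & re >= 100]
  if (length(eligible) == 0) {
    "none"
  } else if (length(eligible) == 1L) {
    names(eligible)
  } else if (eligible[["method1"]] >= eligible[["method3"]]) {
    "method1" # tie-break toward the design-structure method
  } else {
    "method3"
  }
}

#' Choose and apply the better spatial adjustment
#'
#' Computes both adjustments and their relative efficiencies, then applies
#' the three-rule criterion: if both RE < 100, no adjustment; if exactly
#' one RE >= 100, that method; if both >= 100, the higher RE (ties go to
#' Method I, which uses the design structure). If Method III is unavailable
#' (too few blocks or constant secondary checks) only Method I is
#' considered.
#'
#' @inheritParams method3_adjust
#' @return An object of class `adjustment_decision`: a list with `chosen`
#'   (`"none"`, `"method1"` or `"method3"`), `re` (named RE values),
#'   `table` (the input with `value_adj` set to the chosen adjustment, or
#'   the raw values if none), and the per-method fits. Has [tidy()] and
#'   [glance()] methods.
#' @export
select_adjustment <- function(table, check2_reference = c("grand", "block")) {
  check2_reference <- match.arg(check2_reference)
  iwp_raw <- iwp_error(table, "value")

  m1 <- method1_adjust(table)
  re <- c(method1 = relative_efficiency(iwp_raw, iwp_error(m1, "value_adj")))
  fits <- list(method1 = attr(m1, "fit"))
  tables <- list(method1 = m1)

  m3 <- tryCatch(
    method3_adjust(table, check2_reference = check2_reference),
    canopytrial_method3_unavailable = function(e) NULL
  )
  if (!is.null(m3)) {
    re["method3"] <- relative_efficiency(iwp_raw, iwp_error(m3, "value_adj"))
    fits$method3 <- attr(m3, "fit")
    tables$method3 <- m3
  } else {
    re["method3"] <- NA_real_
  }

  chosen <- choose_adjustment_method(re["method1"], re["method3"])

  out <- if (chosen == "none") {
    dplyr::mutate(table, value_adj = .data$value)
  } else {
    tables[[chosen]]
  }
  structure(
    list(chosen = chosen, re = re, iwp_original = iwp_raw,
         table = tibble::as_tibble(out), fits = fits),
    class = "adjustment_decision"
  )
}

#' Spatially adjust a multi-stratum trial
#'
#' Applies [select_adjustment()] independently within each stratum
#' (location x spacing by default), mirroring trials laid out at several
#' sites or densities.
#'
#' @param table Plot table covering one trait across one or more strata.
#' @param stratify Character vector of stratum columns present in `table`.
#' @inheritParams method3_adjust
#' @return A list with `table` (all strata, `value_adj` set per stratum)
#'   and `decisions` (one tidy row per stratum: REs and chosen method).
#' @export
adjust_trial <- function(table, stratify = c("location", "spacing"),
                         check2_reference = c("grand", "block")) {
  check2_reference <- match.arg(check2_reference)
  stratify <- intersect(stratify, names(table))
  groups <- if (length(stratify) == 0) {
    list(table)
  } else {
    table |>
      dplyr::group_by(dplyr::across(dplyr::all_of(stratify))) |>
      dplyr::group_split()
  }
  decisions <- purrr::map(groups, function(g) {
    dec <- select_adjustment(g, check2_reference = check2_reference)
    lab <- dplyr::distinct(g, dplyr::across(dplyr::all_of(stratify)))
    list(table = dec$table, row = dplyr::bind_cols(lab, tidy(dec)))
  })
  list(
    table = dplyr::bind_rows(purrr::map(decisions, "table")),
    decisions = dplyr::bind_rows(purrr::map(decisions, "row"))
  )
}

#' @method tidy adjustment_decision
#' @export
tidy.adjustment_decision <- function(x, ...) {
  tibble::tibble(
    re_method1 = unname(x$re["method1"]),
    re_method3 = unname(x$re["method3"]),
    iwp_original = x$iwp_original,
    chosen = x$chosen
  )
}

#' @method glance adjustment_decision
#' @export
glance.adjustment_decision <- function(x, ...) tidy(x)

#' @method tidy mad_method1
#' @export
tidy.mad_method1 <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "grand_mean", index = NA_integer_, estimate = x$grand_mean),
    tibble::tibble(term = "row_mean", index = x$row_means$block_row,
                   estimate = x$row_means$r),
    tibble::tibble(term = "col_mean", index = x$col_means$block_col,
                   estimate = x$col_means$c)
  )
}

#' @method glance mad_method1
#' @export
glance.mad_method1 <- function(x, ...) {
  tibble::tibble(grand_mean = x$grand_mean,
                 n_rows = nrow(x$row_means), n_cols = nrow(x$col_means))
}

#' @method tidy mad_method3
#' @export
tidy.mad_method3 <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

#' @method glance mad_method3
#' @export
glance.mad_method3 <- function(x, ...) {
  tibble::tibble(beta = x$beta, alpha = x$alpha,
                 n_blocks = nrow(x$per_block),
                 check2_reference = x$check2_reference)
}

#' @export
print.adjustment_decision <- function(x, ...) {
  cat("MAD spatial-adjustment decision\n")
  cat(sprintf("  RE (Method I):   %s\n", format(x$re["method1"])))
  cat(sprintf("  RE (Method III): %s\n", format(x$re["method3"])))
  cat(sprintf("  chosen: %s\n", x$chosen))
  invisible(x)
}
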