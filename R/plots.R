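#' Map a MAD field layout
#'
#' @param layout A layout from [generate_layout()] (optionally with a
#'   `value` column from [simulate_trial()]).
#' @param fill `"role"` (default) colours check and test plots;
#'   `"value"` shades plots by trait value if present.
#' @return A ggplot tile map of the field, one tile per plot.
#' @export
plot_field_layout <- function(layout, fill = c("role", "value")) {
  fill <- match.arg(fill)
  if (fill == "value" && !"value" %in% names(layout)) {
    abort("`layout` has no `value` column; simulate a trial first.")
  }
  ggplot2::ggplot(layout, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill]]),
                       colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Field column", y = "Field row", fill = fill)
}
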