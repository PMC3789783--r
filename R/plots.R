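#' Plot a time-resolved observable
#'
#' Line plot of any per-frame series produced by the package (chi angles,
#' kink angles, hydration counts, RMSD). The value column is picked
#' automatically (`value`, `kink`, `count` or `rmsd`); switch events can be
#' overlaid as vertical lines.
#'
#' @param series Tibble with `time_ns` and one value column.
#' @param events Optional event tibble from [detect_switches()].
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_series <- function(series, events = NULL, ylab = NULL) {
  vcol <- intersect(c("value", "kink", "count", "rmsd"), names(series))[1]
  if (is.na(vcol))
    rlang::abort("no value column found", class = "gpcrtraj_type_error")
  p <- ggplot2::ggplot(series, ggplot2::aes(.data$time_ns, .data[[vcol]])) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (ns)", y = ylab %||% vcol) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0)
    p <- p + ggplot2::geom_vline(xintercept = events$time_ns,
                                 linetype = "dashed", colour = "firebrick")
  p
}

#' Overlay an observable across conditions
#'
#' @param comparison Result of [compare_conditions()].
#' @param observable Observable name as it appears in `comparison$long`
#'   (e.g. `"kink"` or `"hydration:D2.50"`).
#' @return A ggplot object.
#' @export
plot_condition_overlay <- function(comparison, observable) {
  df <- dplyr::filter(comparison$long, .data$observable == !!observable)
  if (nrow(df) == 0)
    rlang::abort(paste0("observable not found: ", observable),
                 class = "gpcrtraj_comparison_error")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ns, .data$value,
                                   colour = .data$condition)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (ns)", y = observable) +
    ggplot2::theme_minimal()
}
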