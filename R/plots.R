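#' Bland-Altman plot
#'
#' Scatter of pair means against pair differences with horizontal lines
#' at the bias and the two limits of agreement. Rendering is a
#' deterministic function of the report.
#'
#' @param report A [bland_altman()] object.
#' @param pairs Optional tibble with `mean` and `diff` columns; defaults
#'   to the pairs stored in the report.
#' @param file Optional output path (`.png` or `.svg`); when given, the
#'   figure is written there and the path returned invisibly.
#' @param width,height,dpi Device size (inches) and resolution.
#' @return The ggplot object (or, with `file`, the path invisibly).
#' @export
bland_altman_plot <- function(report, pairs = NULL, file = NULL,
                              width = 6, height = 4, dpi = 150) {
  stopifnot(inherits(report, "bland_altman"))
  pairs <- pairs %||% report$pairs
  if (is.null(pairs) || nrow(pairs) == 0)
    stop_bodyscan("input_error", "no pairs to plot")
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = report$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(report$loa_low, report$loa_high),
                        linetype = "dashed", linewidth = 0.5) +
    ggplot2::labs(
      x = "Mean of the two methods",
      y = "Difference between methods",
      title = sprintf("Bland-Altman: bias %.3f, LoA %.3f to %.3f",
                      report$mean_diff, report$loa_low, report$loa_high)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
    return(invisible(file))
  }
  p
}

#' @rdname bland_altman_plot
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @export
autoplot.bland_altman <- function(object, ...) {
  bland_altman_plot(object)
}
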