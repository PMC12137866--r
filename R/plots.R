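# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scan pattern's spatio-temporal order
#'
#' Tiles the pixel grid coloured by visit time within the first frame,
#' mirroring the rainbow schematics used to illustrate raster vs interleaved
#' fluence distribution.
#'
#' @param object A `scan_pattern`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_pattern <- function(object, ...) {
  npx <- object$nx * object$ny
  v <- utils::head(object$visits, npx)
  ggplot2::ggplot(v, ggplot2::aes(.data$x, .data$y,
                                  fill = .data$t_start_ns / 1e3)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "visit time (µs)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s scan, %s integration", object$mode,
                                  object$integration),
                  x = "x (fast axis)", y = "y (slow axis)") +
    ggplot2::theme_minimal()
}

#' Plot a phantom map
#'
#' @param object A `phantom`.
#' @param map `"yield"`, `"tau"` or `"label"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phantom <- function(object, map = c("yield", "tau", "label"), ...) {
  map <- match.arg(map)
  m <- switch(map, yield = object$yield_map, tau = log10(object$tau_map),
              label = object$label_map)
  df <- tibble::tibble(x = rep(0:(object$nx - 1), each = object$ny),
                       y = rep(0:(object$ny - 1), object$nx),
                       value = as.numeric(m))
  lab <- switch(map, yield = "SE yield", tau = "log10 tau (ns)",
                label = "label")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("phantom '%s' (%s)", object$preset, map)) +
    ggplot2::theme_minimal()
}

#' Plot an acquired or processed image
#'
#' @param object A `subframe_stack` or matrix.
#' @param frame Frame index (stacks).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_frame <- function(object, frame = 1L, ...) {
  m <- if (is.matrix(object)) object else as_frame_array(object)[, , frame]
  df <- tibble::tibble(x = rep(seq_len(ncol(m)) - 1, each = nrow(m)),
                       y = rep(seq_len(nrow(m)) - 1, ncol(m)),
                       value = as.numeric(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "counts") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a strategy comparison
#'
#' Charging deviation (distance of the histogram mean from the 8-bit
#' mid-range 127) per strategy, schedule and seed; lower is better.
#'
#' @param object A `strategy_comparison`.
#' @param metric Column of the report to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strategy_comparison <- function(object,
                                         metric = "charging_deviation", ...) {
  df <- object$report |>
    dplyr::mutate(schedule = sprintf("%g ns x %d", .data$dwell_ns,
                                     .data$reps))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data[[metric]],
                                   colour = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey40") +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$schedule)) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a peak-charge trace
#'
#' @param trace Tibble from [peak_charge_trace()], optionally with a
#'   `condition` column to colour by.
#' @return A ggplot.
#' @export
plot_peak_charge <- function(trace) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$update, .data$peak_charge))
  if ("condition" %in% names(trace))
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$condition))
  else p <- p + ggplot2::geom_line()
  p + ggplot2::labs(x = "dissipation update",
                    y = "peak local charge (electrons)") +
    ggplot2::theme_minimal()
}
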