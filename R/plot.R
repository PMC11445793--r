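#' Plot a dream chart with peak/trough shading and trendline
#'
#' Line plot of the standardized valence sequence against the chronological
#' axis, with the zero midline drawn, peaks shaded distinctly from troughs,
#' optional vertical trapezoid rules inside each shaded excursion, and an
#' optional polynomial trendline overlay.
#'
#' @param chart chart tibble for a single report (columns `x`, `y`; a
#'   `report_id` column is used for the title if present).
#' @param segments optional segmentation rows for the same report (from
#'   [segment_charts()]); enables the shading.
#' @param trend optional one-row trend fit (from [fit_trends()]); enables
#'   the trendline overlay.
#' @param trapezoids draw the vertical mini-trapezoid rules inside shaded
#'   segments.
#' @return a ggplot object.
#' @examples
#' ch <- data.frame(report_id = "d1", x = 1:7, y = c(0, 1, 2, 0, -1, -2, 0))
#' plot_dream_chart(ch, segment_charts(ch), fit_trends(ch))
#' @export
plot_dream_chart <- function(chart, segments = NULL, trend = NULL,
                             trapezoids = FALSE) {
  stopifnot(is.data.frame(chart), all(c("x", "y") %in% names(chart)))
  title <- if ("report_id" %in% names(chart)) unique(chart$report_id)[1] else NULL
  p <- ggplot2::ggplot(chart, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey40", linewidth = 0.3)
  if (!is.null(segments) && nrow(segments) > 0) {
    shade <- segments |>
      dplyr::mutate(.seg = dplyr::row_number()) |>
      dplyr::select("kind", "points", ".seg") |>
      tidyr::unnest("points")
    p <- p + ggplot2::geom_ribbon(
      data = shade,
      ggplot2::aes(x = .data$x, ymin = pmin(.data$y, 0), ymax = pmax(.data$y, 0),
                   group = .data$.seg, fill = .data$kind),
      alpha = 0.45, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(
        values = c(peak = "#7b3fa0", trough = "#e08214"), name = NULL
      )
    if (trapezoids) {
      p <- p + ggplot2::geom_segment(
        data = shade,
        ggplot2::aes(x = .data$x, xend = .data$x, y = 0, yend = .data$y,
                     group = .data$.seg),
        color = "grey25", linewidth = 0.2, inherit.aes = FALSE
      )
    }
  }
  p <- p + ggplot2::geom_line(linewidth = 0.5) + ggplot2::geom_point(size = 0.8)
  if (!is.null(trend) && nrow(trend) == 1 && isTRUE(nrow(chart) > 1)) {
    cf <- trend$coefficients[[1]]
    grid <- tibble::tibble(x = seq(min(chart$x), max(chart$x), length.out = 200))
    grid$y <- .polyval(cf, grid$x)
    p <- p + ggplot2::geom_line(data = grid, color = "#1b6ca8",
                                linewidth = 0.7, linetype = "dashed")
  }
  p + ggplot2::labs(x = "chronological position (window)",
                    y = "standardized valence", title = title) +
    ggplot2::theme_minimal()
}

#' Faceted dream charts for a whole pipeline run
#'
#' @param object a `dream_analysis` object.
#' @param trend overlay the fitted trendlines.
#' @param ... unused.
#' @return a ggplot object faceted by report.
#' @method autoplot dream_analysis
#' @export
autoplot.dream_analysis <- function(object, trend = TRUE, ...) {
  shade <- object$segments |>
    dplyr::group_by(.data$report_id) |>
    dplyr::mutate(.seg = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("report_id", "kind", "points", ".seg") |>
    tidyr::unnest("points")
  p <- ggplot2::ggplot(object$charts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey40", linewidth = 0.3)
  if (nrow(shade) > 0) {
    p <- p + ggplot2::geom_ribbon(
      data = shade,
      ggplot2::aes(x = .data$x, ymin = pmin(.data$y, 0), ymax = pmax(.data$y, 0),
                   group = .data$.seg, fill = .data$kind),
      alpha = 0.45, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(
        values = c(peak = "#7b3fa0", trough = "#e08214"), name = NULL
      )
  }
  p <- p + ggplot2::geom_line(linewidth = 0.4)
  if (trend) {
    trendlines <- object$trends |>
      dplyr::filter(purrr::map_int(.data$coefficients, length) > 1) |>
      dplyr::inner_join(
        object$charts |>
          dplyr::group_by(.data$report_id) |>
          dplyr::summarise(.x0 = min(.data$x), .x1 = max(.data$x),
                           .groups = "drop"),
        by = "report_id"
      )
    if (nrow(trendlines) > 0) {
      grid <- trendlines |>
        dplyr::rowwise() |>
        dplyr::reframe(
          report_id = .data$report_id,
          x = seq(.data$.x0, .data$.x1, length.out = 100),
          y = .polyval(.data$coefficients[[1]],
                       seq(.data$.x0, .data$.x1, length.out = 100))
        )
      p <- p + ggplot2::geom_line(data = grid, color = "#1b6ca8",
                                  linewidth = 0.5, linetype = "dashed")
    }
  }
  p + ggplot2::facet_wrap(~report_id, scales = "free") +
    ggplot2::labs(x = "chronological position (window)",
                  y = "standardized valence") +
    ggplot2::theme_minimal()
}

#' Heatmap of indicator-by-variable correlations
#'
#' Tile plot of the correlation table, with significant pairs outlined —
#' the flat stand-in for a network diagram of indicators and external
#' variables.
#'
#' @param correlations tibble from [correlate_indicators()].
#' @return a ggplot object.
#' @export
plot_correlations <- function(correlations) {
  stopifnot(is.data.frame(correlations),
            all(c("indicator", "variable", "coefficient") %in% names(correlations)))
  ggplot2::ggplot(correlations,
                  ggplot2::aes(x = .data$variable, y = .data$indicator,
                               fill = .data$coefficient)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_tile(
      data = dplyr::filter(correlations, .data$significant),
      fill = NA, color = "black", linewidth = 0.6
    ) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$coefficient,
                      ifelse(.data$significant, "*", ""))
    ), size = 2.8) +
    ggplot2::scale_fill_gradient2(low = "#e08214", mid = "white",
                                  high = "#7b3fa0", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
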