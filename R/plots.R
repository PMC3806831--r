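#' Plot the correlation / scan-duration trade-off
#'
#' Bar plot of the best combinations ranked by correlation, with the total
#' scan duration of each combination overlaid as a line on a rescaled
#' secondary axis.
#'
#' @param object a [evaluate_combinations()] table.
#' @param top_k combinations to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.combination_results <- function(object, top_k = 10, ...) {
  top <- rank_combinations(object, "by_correlation", top_k = top_k)
  top$subset <- factor(top$subset, levels = top$subset)
  sc <- max(top$scan_minutes) / max(top$r)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$subset)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$r), fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.2, linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$scan_minutes / sc, group = 1),
                       color = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$scan_minutes / sc),
                        color = "firebrick") +
    ggplot2::scale_y_continuous(
      "Pearson correlation (volume vs reference)",
      sec.axis = ggplot2::sec_axis(~ . * sc, name = "scan duration (min)")
    ) +
    ggplot2::labs(x = NULL,
                  title = "Best contrast-weighting combinations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the performance-versus-protocol-size curve
#'
#' Best correlation achieved at each subset size, annotated with that
#' subset's scan duration: the rises-then-plateaus pattern that motivates
#' choosing a small informative protocol.
#'
#' @param results a [evaluate_combinations()] table.
#' @return A ggplot object.
#' @export
plot_size_tradeoff <- function(results) {
  bc <- rank_combinations(results, "by_count")
  ggplot2::ggplot(bc, ggplot2::aes(x = .data$n_weightings, y = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$scan_minutes),
                        color = "steelblue") +
    ggplot2::scale_x_continuous(breaks = bc$n_weightings) +
    ggplot2::labs(x = "number of contrast weightings",
                  y = "best Pearson correlation",
                  size = "scan (min)") +
    ggplot2::theme_minimal()
}

#' Display one slice channel with wall and plaque overlays
#'
#' @param slice a [vessel_slice()].
#' @param channel channel name to display.
#' @param predicted optional logical matrix of predicted plaque pixels.
#' @return A ggplot object: the channel as a raster, the reference
#'   soft-plaque pixels outlined in yellow, predictions (if given) in red.
#' @export
plot_slice <- function(slice, channel = names(slice$channels)[1],
                       predicted = NULL) {
  stopifnot(inherits(slice, "vessel_slice"),
            channel %in% names(slice$channels))
  g <- slice$geometry
  df <- tidyr::expand_grid(row = seq_len(g$rows), col = seq_len(g$cols))
  df$intensity <- as.vector(slice$channels[[channel]])
  df$wall <- as.vector(slice$wall)
  df$plaque <- as.vector(slice$labels == 2L)
  if (!is.null(predicted)) df$predicted <- as.vector(predicted)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = df[df$plaque, ], color = "yellow",
                        size = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = channel, x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(predicted)) {
    p <- p + ggplot2::geom_point(data = df[df$predicted, ], color = "red",
                                 size = 0.2)
  }
  p
}
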