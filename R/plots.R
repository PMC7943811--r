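## ggplot2 views of the result types.

#' @export
autoplot.metric_curves <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_discrete(
      labels = c(r_cc = "R[cc]", r_iu = "R[iu]", ua = "UA")) +
    ggplot2::labs(x = "uncertainty threshold", y = "metric value",
                  colour = NULL,
                  title = "Uncertainty-quality metrics over the threshold sweep") +
    ggplot2::ylim(0, 1)
}

#' @export
autoplot.referral_curve <- function(object, baseline = NULL, ...) {
  xvar <- if (attr(object, "mode") == "by_tolerance") "tolerance"
          else "fraction"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[xvar]], y = .data$accuracy)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(
      x = if (xvar == "tolerance") "tolerated uncertainty"
          else "fraction of retained data",
      y = "accuracy on retained items",
      title = "Uncertainty-informed referral")
  if (!is.null(baseline) && xvar == "fraction") {
    p <- p +
      ggplot2::geom_ribbon(
        data = baseline,
        ggplot2::aes(x = .data$fraction,
                     ymin = .data$mean_accuracy - .data$sd_accuracy,
                     ymax = .data$mean_accuracy + .data$sd_accuracy),
        inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::geom_line(
        data = baseline,
        ggplot2::aes(x = .data$fraction, y = .data$mean_accuracy),
        inherit.aes = FALSE, linetype = "dashed")
  }
  p
}

#' @export
autoplot.convergence_curve <- function(object, ...) {
  det <- attr(object, "deterministic_error")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$T, y = .data$mean_error)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_error - .data$sd_error,
                                      ymax = .data$mean_error + .data$sd_error),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = det, linetype = "dotted") +
    ggplot2::labs(x = "number of MC passes (T)", y = "test error",
                  title = "Convergence of MC averaging",
                  subtitle = "dotted line: deterministic (no-drop) baseline")
}

#' Heat-map view of a per-pixel uncertainty or label map
#'
#' @param map Numeric matrix (e.g. an element of [as_label_maps()]).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_pixel_map <- function(map, title = "pixel map") {
  df <- expand.grid(row = seq_len(nrow(map)), col = seq_len(ncol(map)))
  df$value <- as.vector(map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL)
}
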