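#' Plot a prevalence-sweep curve
#'
#' Metric value against prevalence at fixed sensitivity and specificity,
#' with the balanced point (prevalence 0.5) marked by a dot.
#'
#' @param object,x A `sweep_curve` from [prevalence_sweep()].
#' @param mark_balanced Mark the value at prevalence 0.5.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' curve <- prevalence_sweep("mcc", 0.71, 0.89, grid_size = 51)
#' autoplot(curve)
#' @importFrom ggplot2 autoplot
#' @method autoplot sweep_curve
#' @export
autoplot.sweep_curve <- function(object, mark_balanced = TRUE, ...) {
  metric <- attr(object, "metric")
  sen <- attr(object, "sen")
  spe <- attr(object, "spe")
  p <- ggplot2::ggplot(as.data.frame(object),
                       ggplot2::aes(x = .data$prevalence, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = "positive prevalence",
      y = metric,
      title = sprintf("%s vs prevalence (sen = %s, spe = %s)",
                      metric, format(sen), format(spe))
    ) +
    ggplot2::theme_minimal()
  if (mark_balanced) {
    bal <- tryCatch(
      calibrated_metric(metric, sen, spe, target_prevalence = 0.5),
      prevcal_error = function(e) NA_real_)
    if (!is.na(bal)) {
      p <- p + ggplot2::annotate("point", x = 0.5, y = bal, size = 2.5)
    }
  }
  p
}

#' @rdname autoplot.sweep_curve
#' @export
plot.sweep_curve <- function(x, ...) {
  print(autoplot.sweep_curve(x, ...))
  invisible(x)
}

#' @export
ggplot2::autoplot
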