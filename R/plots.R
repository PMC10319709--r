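#' Plot precision-recall curves with decision-threshold annotations
#'
#' @param scores named list of score vectors (one per model).
#' @param labels 0/1 outcomes.
#' @param annotate_at decision thresholds to mark with labelled dots.
#' @return a ggplot object.
#' @export
plot_pr_curves <- function(scores, labels, annotate_at = c(0.02, 0.05, 0.1)) {
  if (!is.list(scores)) scores <- list(model = scores)
  curves <- data.table::rbindlist(lapply(names(scores), function(m) {
    pc <- pr_curve(scores[[m]], labels, annotate_at)
    cbind(model = m, pc$curve)
  }))
  dots <- data.table::rbindlist(lapply(names(scores), function(m) {
    pc <- pr_curve(scores[[m]], labels, annotate_at)
    cbind(model = m, pc$annotations)
  }))
  ggplot2::ggplot(curves, ggplot2::aes(x = recall, y = precision,
                                       colour = model)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = dots, size = 2) +
    ggplot2::geom_text(data = dots,
                       ggplot2::aes(label = signif(threshold, 2)),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Recall (sensitivity)",
                  y = "Precision (positive predictive value)") +
    ggplot2::theme_minimal()
}

#' Plot a LOWESS calibration curve with its 99th-percentile marker
#'
#' @param probabilities predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param fraction LOWESS span.
#' @return a ggplot object.
#' @export
plot_calibration <- function(probabilities, labels, fraction = 0.6) {
  cal <- calibration_curve(probabilities, labels, fraction)
  ggplot2::ggplot(cal$curve, ggplot2::aes(x = predicted, y = observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = cal$percentile_99,
                        linetype = "dotted", colour = "firebrick") +
    ggplot2::labs(x = "Predicted probability",
                  y = "Smoothed observed rate",
                  subtitle = sprintf("dotted line: 99th percentile of predictions (%.4f)",
                                     cal$percentile_99)) +
    ggplot2::theme_minimal()
}
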