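#' Plot distance-to-equator trajectories
#'
#' One curve per chromosome, colored by trajectory class when available;
#' the side view that makes retracing excursions and equator crossings
#' visible.
#'
#' @param aligned Aligned trajectory tibble.
#' @param signed Plot signed z (default) or |z|.
#' @return A ggplot.
#' @export
plot_trajectories <- function(aligned, signed = TRUE) {
  df <- mutate(aligned, yval = if (signed) .data$z_um else
    abs(.data$z_um))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$yval,
                                        group = .data$chromosome_id))
  if ("true_label" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$true_label),
                                alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.8)
  }
  p + ggplot2::labs(x = "time since GVBD (min)",
                    y = if (signed) "distance to equator plane (um, signed)"
                        else "distance to equator plane (um)",
                    color = "trajectory") +
    ggplot2::theme_minimal()
}

#' Plot population speed components with confidence bands
#'
#' Mean curves with 95% CI ribbons, faceted by component, optionally with
#' step boundaries overlaid.
#'
#' @param summary Tibble from [summarize_population()].
#' @param segmentation Optional [segment_steps()] result.
#' @return A ggplot.
#' @export
plot_speed_summary <- function(summary, segmentation = NULL) {
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$t_mid_min,
                                             y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time since GVBD (min)", y = "speed (um/min)") +
    ggplot2::theme_minimal()
  if (!is.null(segmentation) && segmentation$status != "undetermined") {
    p <- p + ggplot2::geom_vline(xintercept = segmentation$boundaries,
                                 linetype = "dashed", color = "grey40")
  }
  p
}

#' ROC curves of a classifier evaluation
#'
#' @param object A `classifier_evaluation`.
#' @param ... Unused.
#' @return A ggplot of the one-vs-rest ROC curve per class.
#' @method autoplot classifier_evaluation
#' @export
autoplot.classifier_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                           color = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  color = "class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
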