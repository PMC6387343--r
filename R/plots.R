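#' Plot an IMU recording
#'
#' Six stacked traces (triaxial acceleration and angular velocity), with
#' subphase intervals shaded when an annotation is supplied (the
#' recording's ground truth is used when present and no annotation is
#' given).
#'
#' @param object An [imu_recording()].
#' @param annotation Optional [subphase_annotation()] to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.imu_recording <- function(object, annotation = NULL, ...) {
  if (is.null(annotation)) annotation <- rec_truth(object)
  long <- tidyr::pivot_longer(as_tibble(object), -"t",
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel,
                         levels = c("acc_ap", "acc_ml", "acc_v",
                                    "gyr_ap", "gyr_ml", "gyr_v"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        strip.position = "right") +
    ggplot2::labs(
      x = "time [s]", y = NULL,
      title = sprintf("%s recording, subject %s", rec_test_type(object),
                      rec_subject_id(object))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(annotation) && nrow(annotation$intervals)) {
    iv <- annotation$intervals
    p <- p + ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   fill = .data$label),
      ymin = -Inf, ymax = Inf, alpha = 0.18, inherit.aes = FALSE
    )
  }
  p + ggplot2::geom_line(linewidth = 0.3)
}

#' Plot the AUCs of a model report
#'
#' Point-and-interval display of the discriminative ability (AUC with 95%
#' CI) of the standard clinical, instrumented and combined models, per
#' test, with the chance level marked.
#'
#' @param object A `model_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.model_report <- function(object, ...) {
  aucs <- glance(object)
  aucs$model <- factor(aucs$model,
                       levels = c("standard", "instrumented", "combined"))
  ggplot2::ggplot(aucs, ggplot2::aes(x = .data$model, y = .data$auc,
                                     colour = .data$model)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::facet_wrap(~test) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "AUC (95% CI)",
                  title = "Discrimination of High vs Very High Functional Status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot detected vs true subphases
#'
#' Companion diagnostic for segmentation: two tracks of intervals, the
#' detected annotation above the ground truth.
#'
#' @param detected,truth [subphase_annotation()] objects.
#' @return A ggplot.
#' @export
plot_segmentation <- function(detected, truth) {
  both <- bind_rows(
    mutate(detected$intervals, source = "detected"),
    mutate(truth$intervals, source = "truth")
  )
  ggplot2::ggplot(both) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_s, xend = .data$end_s,
                   y = .data$source, yend = .data$source,
                   colour = .data$label),
      linewidth = 6
    ) +
    ggplot2::labs(x = "time [s]", y = NULL, colour = "subphase") +
    ggplot2::theme_minimal()
}
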