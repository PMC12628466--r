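#' Plot an oxygen dissociation curve
#'
#' Saturation against pO2 with a vertical reference at the adjusted p50 and
#' a horizontal line at 50% saturation.
#'
#' @param object An `odc_curve` from [build_odc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.odc_curve <- function(object, ...) {
  p50 <- attr(object, "p50")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$po2, y = .data$saturation)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = p50, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey40") +
    ggplot2::annotate("text", x = p50, y = 0.05,
                      label = sprintf("p50 = %.2f mmHg", p50), hjust = -0.05, size = 3) +
    ggplot2::labs(x = expression(pO[2] ~ "(mmHg)"), y = "Hb saturation") +
    ggplot2::theme_minimal()
}

#' Plot a glycolytic-flux timecourse summary
#'
#' Cell means with +/- 1 SE error bars per condition across the study
#' timepoints.
#'
#' @param summary Output of [summarize_timecourse()].
#' @param timepoint_levels Optional ordering of timepoints on the x axis.
#' @return A ggplot object.
#' @export
plot_flux_timecourse <- function(summary, timepoint_levels = NULL) {
  d <- as_tibble(summary)
  if (!is.null(timepoint_levels)) {
    d$timepoint <- factor(d$timepoint, levels = timepoint_levels)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint, y = .data$mean_flux,
                                  colour = .data$condition,
                                  group = .data$condition)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_flux - .data$se_flux,
                   ymax = .data$mean_flux + .data$se_flux),
      width = 0.15, position = ggplot2::position_dodge(0.2)) +
    ggplot2::labs(x = NULL, y = expression("Glycolytic flux (" * mu * "M/min)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a NIRS summary
#'
#' Long-format view of the baseline, bin and recovery values per signal.
#'
#' @param object A `nirs_summary` from [nirs_exercise_summary()] or
#'   [nirs_occlusion_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nirs_summary <- function(object, ...) {
  d <- as_tibble(object)
  d$point <- factor(d$point, levels = unique(d$point))
  long <- tidyr::pivot_longer(d, c("O2Hb", "HHb", "tHb"),
                              names_to = "signal", values_to = "uM")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$point, y = .data$uM,
                                     colour = .data$signal,
                                     group = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = expression(Delta * "[Hb] (" * mu * "M)"),
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
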