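#' Plot a CoM tracking series
#'
#' Time course of the normalized center of mass, with the indifference
#' level 0.5 marked; optionally shades the steady-state averaging window.
#'
#' @param object A `com_series`.
#' @param window Optional [odor_window()] (or odor name) to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot com_series
autoplot.com_series <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s / 60, y = .data$com)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (min)", y = "CoM (0 = odorant end)") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    if (is.character(window)) window <- default_window(window)
    p <- p + ggplot2::annotate("rect",
                               xmin = window$start_min, xmax = window$end_min,
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "steelblue")
  }
  p
}

#' Plot a group-size calibration
#'
#' Replicate variance and effect size against flies per tube, the two
#' panels used to choose the working group size (minimal variance, maximal
#' effect).
#'
#' @param object A `fly_calibration` from [calibrate_group_size()].
#' @param ... Unused.
#' @return A ggplot (facetted).
#' @export
#' @method autoplot fly_calibration
autoplot.fly_calibration <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object)[c("group_size", "variance", "effect_size")],
    cols = c("variance", "effect_size"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = c("variance", "effect_size"),
                        labels = c("Replicate variance", "Effect size (Cohen's d)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group_size, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = unique(long$group_size)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Flies per tube", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evoked trace with its quantification
#'
#' @param object An `evoked_trace`.
#' @param peak Optional `peak_response` from [quantify_peak()] to annotate.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot evoked_trace
autoplot.evoked_trace <- function(object, peak = NULL, ...) {
  stim <- attr(object, "stim_time")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = stim, linetype = "dotted") +
    ggplot2::labs(x = "Time (s)",
                  y = sprintf("Signal (%s)", attr(object, "unit")),
                  title = sprintf("%s trace", toupper(attr(object, "modality")))) +
    ggplot2::theme_minimal()
  if (!is.null(peak)) {
    p <- p +
      ggplot2::geom_hline(yintercept = peak$baseline_mean,
                          linetype = "dashed", colour = "grey50") +
      ggplot2::annotate("point", x = peak$peak_time_s,
                        y = object$signal[which.min(abs(object$time_s - peak$peak_time_s))],
                        colour = "red")
  }
  p
}
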