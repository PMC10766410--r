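#' Plot a frequent-sampling series with its detected pulses
#'
#' Concentration over time with the GnRH bolus marked; detected pulse peaks
#' and nadirs are overlaid when a call set is supplied. Requires ggplot2.
#'
#' @param series A [hormone_series()].
#' @param callset Optional `pulse_callset` for the same series.
#' @return A ggplot object.
#' @export
plot_series <- function(series, callset = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_series requires the ggplot2 package", call. = FALSE)
  }
  tb <- series_tibble(series)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$time_min,
                                        y = .data$value_iu_l)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Time (min)", y = sprintf("%s (IU/L)", series$hormone),
      title = sprintf("%s / %s visit", series$subject_id, series$visit)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(series$gnrh_time)) {
    p <- p + ggplot2::geom_vline(xintercept = series$gnrh_time,
                                 linetype = "dashed", colour = "firebrick")
  }
  if (!is.null(callset) && nrow(callset$pulses)) {
    p <- p +
      ggplot2::geom_point(
        data = callset$pulses,
        ggplot2::aes(x = .data$peak_time, y = .data$peak_value),
        colour = "firebrick", shape = 17, size = 2
      ) +
      ggplot2::geom_point(
        data = callset$pulses,
        ggplot2::aes(x = .data$nadir_time, y = .data$nadir_value),
        colour = "steelblue", shape = 25, size = 2
      )
  }
  p
}
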