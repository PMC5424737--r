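#' Plot an enhancement result
#'
#' Overlays the contaminated input and the enhanced signal; with
#' `artifact = TRUE` the artifact estimate is shown as a third trace.
#'
#' @param object A `ppg_enhanced` tibble.
#' @param artifact Also draw the artifact estimate?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppg_enhanced <- function(object, artifact = FALSE, ...) {
  cols <- c("input", "enhanced", if (artifact) "artifact")
  long <- tidyr::pivot_longer(object[c("time", cols)],
                              -"time", names_to = "series")
  long$series <- factor(long$series, levels = cols)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude", colour = NULL,
      title = paste0("Enhancement (", attr(object, "method"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo metric trends over SNR
#'
#' Mean metric value per method as a function of input SNR, one facet
#' per metric.
#'
#' @param object A `ppg_mc` object from [run_monte_carlo()].
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppg_mc <- function(object,
                            metrics = c("correlation", "f1", "mae_ms"),
                            ...) {
  dat <- dplyr::filter(object$summary, .data$metric %in% metrics)
  ggplot2::ggplot(dat, ggplot2::aes(.data$snr_db, .data$mean,
                                    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "input SNR (dB)", y = "mean over repetitions",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the power spectral density of a signal
#'
#' Periodogram on a log power scale, as used to verify that the
#' harmonic structure of the enhanced signal is recovered.
#'
#' @param data A data frame with a `value` column, or a numeric vector.
#' @param fs Sampling frequency in Hz.
#' @param max_hz Upper frequency limit of the plot.
#' @return A ggplot object.
#' @export
plot_psd <- function(data, fs = signal_fs(data), max_hz = fs / 2) {
  psd <- signal_psd(data, fs = fs)
  psd <- dplyr::filter(psd, .data$frequency <= max_hz,
                       .data$power > 0)
  ggplot2::ggplot(psd, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power density") +
    ggplot2::theme_minimal()
}
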