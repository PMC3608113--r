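#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an RF signal
#'
#' @param object An `rf_signal`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rf_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time * 1e6, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (us)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum in dB
#'
#' @param object An `rf_spectrum` from [signal_spectrum()].
#' @param floor_db Display floor in dB relative to the peak bin.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rf_spectrum <- function(object, floor_db = -100, ...) {
  p <- object$power / max(object$power)
  df <- tibble::tibble(frequency = object$frequency / 1e6,
                       db = pmax(10 * log10(pmax(p, 1e-300)), floor_db))
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (MHz)", y = "power (dB re max)") +
    ggplot2::theme_minimal()
}

#' Plot the components of a basis decomposition
#'
#' @param object A `basis_set`.
#' @param ... Unused.
#' @return A ggplot faceted by component.
#' @export
autoplot.basis_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time * 1e6, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::labs(x = "time (us)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot RMSE versus memory for each method and SNR
#'
#' Mean RMSE (dB) over noise realizations with +-1 sd ribbons, one panel
#' per SNR level, colored by method.
#'
#' @param object An `rmse_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmse_sweep <- function(object, ...) {
  sm <- summarize_sweep(object)
  sm$snr <- factor(ifelse(is.infinite(sm$snr_db), "SNR = Inf",
                          paste0("SNR = ", sm$snr_db, " dB")),
                   levels = unique(ifelse(is.infinite(sm$snr_db), "SNR = Inf",
                                          paste0("SNR = ", sm$snr_db, " dB"))))
  ggplot2::ggplot(sm, ggplot2::aes(.data$memory, .data$mean_rmse_db,
                                   color = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_rmse_db - .data$sd_rmse_db,
                                      ymax = .data$mean_rmse_db + .data$sd_rmse_db,
                                      fill = .data$method),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~snr) +
    ggplot2::labs(x = "memory M", y = "RMSE (dB)") +
    ggplot2::theme_minimal()
}
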