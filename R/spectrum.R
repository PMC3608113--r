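#' One-sided power spectrum of a signal
#'
#' Rectangular-window periodogram. The one-sided power is folded so that
#' `sum(power)` equals the time-domain energy `sum(value^2)` (Parseval under
#' the `|Y(k)|^2 / L` normalization).
#'
#' @param x An `rf_signal` or numeric vector.
#' @param fs Sampling frequency if `x` is numeric.
#' @return A tibble of class `rf_spectrum` with columns `frequency` (Hz) and
#'   `power`.
#' @examples
#' s <- rf_signal(cos(2 * pi * 0.125 * 0:63), fs = 1)
#' sp <- signal_spectrum(s)
#' sp$frequency[which.max(sp$power)] # 0.125
#' @export
signal_spectrum <- function(x, fs = NULL) {
  sv <- sig_values(x, fs)
  v <- sv$value
  L <- length(v)
  if (L < 1L) stop("Empty signal.")
  P <- Mod(stats::fft(v))^2 / L
  nh <- L %/% 2 + 1L                     # bins 0 .. floor(L/2)
  p1 <- P[seq_len(nh)]
  if (L >= 3L) {
    hi <- if (L %% 2 == 0L) (nh - 1L) else nh  # last bin to double (excl. Nyquist if even)
    p1[2:hi] <- p1[2:hi] + P[L - (2:hi) + 2L]
  }
  out <- tibble::tibble(
    frequency = (seq_len(nh) - 1L) * sv$fs / L,
    power = p1
  )
  attr(out, "fs") <- sv$fs
  attr(out, "n") <- L
  class(out) <- c("rf_spectrum", class(out))
  out
}

#' Band energy around a target frequency
#'
#' Sums the one-sided spectral power within `f +- halfwidth`. By default the
#' window is one FFT bin on either side of the bin nearest `f`.
#'
#' @param x An `rf_signal`, numeric vector, or an `rf_spectrum`.
#' @param f Target frequency in Hz.
#' @param halfwidth Half-width of the band in Hz; defaults to `bins` FFT bins.
#' @param bins Band half-width in FFT bins when `halfwidth` is not given.
#' @param fs Sampling frequency if `x` is numeric.
#' @return Summed power in the band (scalar).
#' @export
band_energy <- function(x, f, halfwidth = NULL, bins = 1L, fs = NULL) {
  sp <- if (inherits(x, "rf_spectrum")) x else signal_spectrum(x, fs)
  df <- sp$frequency[2] - sp$frequency[1]
  if (is.null(halfwidth)) halfwidth <- bins * df
  sum(sp$power[abs(sp$frequency - f) <= halfwidth + df * 1e-9])
}
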