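#' Add white Gaussian noise at a prescribed SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise with variance
#' `var(y) / 10^(snr_db / 10)`. `snr_db = Inf` returns the signal unchanged.
#' With `seed` set, the output is reproducible and the caller's RNG state is
#' left untouched.
#'
#' @param y An `rf_signal` or numeric vector.
#' @param snr_db Signal-to-noise ratio in dB (may be `Inf`).
#' @param seed Optional integer seed.
#' @param fs Sampling frequency if `y` is numeric.
#' @return Same type as the input (`rf_signal` in, `rf_signal` out).
#' @export
add_noise <- function(y, snr_db, seed = NULL, fs = NULL) {
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("`snr_db` must be a single number (dB), possibly Inf.")
  if (is.infinite(snr_db)) return(y)
  sv <- sig_values(y, fs)
  sd_w <- sqrt(stats::var(sv$value) / 10^(snr_db / 10))
  draw <- function() stats::rnorm(length(sv$value), 0, sd_w)
  w <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (is.numeric(y)) sv$value + w else {
    out <- y
    out$value <- sv$value + w
    out
  }
}

#' Relative mean square error between a signal and its model
#'
#' The relative mean square error is the residual energy normalized by the
#' signal energy, `mean((yhat - y)^2) / mean(y^2)`, estimated by sample means
#' over the model's valid region (samples at or after the first index where a
#' memory-`M` model is defined). `rmse_db()` returns `10 log10` of the ratio:
#' 0 dB for a zero prediction, large negative values for a good fit.
#'
#' @param y Reference signal (`rf_signal` or numeric).
#' @param yhat Model output, same length and grid as `y`. If it carries a
#'   `valid_from` attribute (as predictions from fitted Volterra models do),
#'   evaluation starts there.
#' @param valid_from 1-based index of the first sample to include; overrides
#'   any `valid_from` attribute on `yhat`. Default 1.
#' @return `rmse()`: the dimensionless ratio. `rmse_db()`: the ratio in dB.
#' @examples
#' y <- rnorm(100)
#' rmse(y, y)      # 0
#' rmse_db(y, 0 * y) # 0 dB
#' @export
rmse <- function(y, yhat, valid_from = NULL) {
  yv <- sig_values(y, fs = 1)$value
  hv <- sig_values(yhat, fs = 1)$value
  if (length(yv) != length(hv))
    stop("`y` and `yhat` must have the same length.")
  if (is.null(valid_from)) valid_from <- attr(yhat, "valid_from")
  if (is.null(valid_from)) valid_from <- 1L
  idx <- seq.int(valid_from, length(yv))
  denom <- mean(yv[idx]^2)
  if (denom == 0) stop("Reference signal has zero energy; RMSE is undefined.")
  mean((hv[idx] - yv[idx])^2) / denom
}

#' @rdname rmse
#' @export
rmse_db <- function(y, yhat, valid_from = NULL) {
  10 * log10(rmse(y, yhat, valid_from))
}
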