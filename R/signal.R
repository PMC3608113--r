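#' Construct an RF signal
#'
#' An `rf_signal` is a tibble with columns `time` (seconds) and `value`
#' (arbitrary linear units, typically Pa for a transmit burst or a normalized
#' amplitude for an echo), carrying the sampling frequency as an attribute.
#' All modeling functions in the package accept either an `rf_signal` or a
#' bare numeric vector plus an `fs` argument.
#'
#' @param value Numeric vector of samples. Must be finite.
#' @param fs Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return A tibble of class `rf_signal` with columns `time` and `value`.
#' @examples
#' s <- rf_signal(sin(2 * pi * 0.1 * 0:99), fs = 1)
#' signal_fs(s)
#' @export
rf_signal <- function(value, fs, t0 = 0) {
  value <- as.numeric(value)
  if (length(value) < 1L) stop("`value` must contain at least one sample.")
  if (!all(is.finite(value))) stop("`value` must be finite.")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz).")
  out <- tibble::tibble(
    time = t0 + (seq_along(value) - 1) / fs,
    value = value
  )
  attr(out, "fs") <- fs
  class(out) <- c("rf_signal", class(out))
  out
}

#' Coerce to an RF signal
#'
#' @param x A numeric vector, an `rf_signal`, or a data frame with columns
#'   `time` and `value` (fs inferred from the time spacing if not given).
#' @param fs Sampling frequency in Hz; required for numeric input.
#' @return An `rf_signal`.
#' @export
as_rf_signal <- function(x, fs = NULL) {
  if (inherits(x, "rf_signal")) return(x)
  if (is.numeric(x)) {
    if (is.null(fs)) stop("`fs` is required when `x` is a bare numeric vector.")
    return(rf_signal(x, fs))
  }
  if (is.data.frame(x) && all(c("time", "value") %in% names(x))) {
    if (is.null(fs)) {
      dt <- diff(x$time)
      if (length(dt) == 0L) stop("Cannot infer `fs` from a single sample.")
      if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
        stop("Non-uniform time grid; supply `fs` explicitly.")
      fs <- 1 / dt[1]
    }
    return(rf_signal(x$value, fs, t0 = x$time[1]))
  }
  stop("Cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to rf_signal.")
}

#' @export
print.rf_signal <- function(x, ...) {
  cat(sprintf("# rf_signal: %d samples at fs = %s Hz (%.3g us)\n",
              nrow(x), format(attr(x, "fs"), big.mark = ","),
              nrow(x) / attr(x, "fs") * 1e6))
  NextMethod()
}

#' Sampling frequency of a signal
#' @param x An `rf_signal` (or data frame with a uniform `time` column).
#' @return Sampling frequency in Hz.
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) fs <- attr(as_rf_signal(x), "fs")
  fs
}

# Internal: extract (values, fs) from flexible signal input.
sig_values <- function(x, fs = NULL) {
  if (is.numeric(x)) {
    list(value = as.numeric(x), fs = fs)
  } else {
    s <- as_rf_signal(x, fs)
    list(value = s$value, fs = attr(s, "fs"))
  }
}

#' Generate a transmit burst
#'
#' Builds the sinusoidal excitation burst used to insonify a microbubble:
#' an integer number of cycles of a sine at the center frequency `f0`,
#' with a rectangular envelope by default. The default settings are an
#' 18-cycle 4 MHz burst at 1.2 MPa sampled at 60 MHz, a regime known to
#' drive contrast microbubbles into sub- and ultraharmonic oscillation
#' while limiting their destruction.
#'
#' @param f0 Center frequency in Hz.
#' @param pressure Peak pressure amplitude in Pa.
#' @param cycles Number of carrier cycles in the burst.
#' @param fs Sampling frequency in Hz; must exceed twice `f0`.
#' @param envelope `"rectangular"` (default) or `"hann"` for a windowed burst.
#' @param phase Carrier phase in radians; the waveform is
#'   `pressure * sin(2 pi f0 t + phase)`.
#' @return An `rf_signal` of length `round(cycles * fs / f0)`, with
#'   attributes `f0` and `pressure`.
#' @examples
#' b <- make_burst(f0 = 4e6, pressure = 1.2e6, cycles = 18, fs = 60e6)
#' nrow(b) # 270 samples: 18 cycles x 15 samples per cycle
#' @export
make_burst <- function(f0 = 4e6, pressure = 1.2e6, cycles = 18, fs = 60e6,
                       envelope = c("rectangular", "hann"), phase = 0) {
  envelope <- match.arg(envelope)
  if (fs <= 2 * f0)
    stop(sprintf("fs = %g Hz cannot sample a carrier at f0 = %g Hz; need fs > 2 f0.",
                 fs, f0))
  if (cycles < 1) stop("`cycles` must be >= 1.")
  if (pressure < 0) stop("`pressure` must be >= 0.")
  n <- round(cycles * fs / f0)
  t <- (0:(n - 1)) / fs
  env <- switch(envelope,
    rectangular = rep(1, n),
    hann = 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
  )
  out <- rf_signal(pressure * sin(2 * pi * f0 * t + phase) * env, fs)
  attr(out, "f0") <- f0
  attr(out, "pressure") <- pressure
  out
}

#' Read / write signals as delimited text
#'
#' The on-disk format is tab-separated text with two columns (`time`,
#' `value`) preceded by a header line `# fs: <Hz>` carrying the sampling
#' frequency.
#'
#' @param x An `rf_signal` (or coercible).
#' @param path File path.
#' @param fs Sampling frequency, if `x` is a bare numeric vector.
#' @return `read_signal` returns an `rf_signal`; `write_signal` returns
#'   `path` invisibly.
#' @export
write_signal <- function(x, path, fs = NULL) {
  s <- if (is.numeric(x)) rf_signal(x, fs) else as_rf_signal(x, fs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.17g", attr(s, "fs")), con)
  utils::write.table(as.data.frame(s[, c("time", "value")]), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  header <- readLines(path, n = 1L)
  fs <- NULL
  if (grepl("^#\\s*fs:", header))
    fs <- as.numeric(sub("^#\\s*fs:\\s*", "", header))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  as_rf_signal(df, fs)
}
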