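# Shared fixtures, built in code.

# Simulated echo for the default study conditions (18-cycle 4 MHz burst at
# 1.2 MPa, 60 MHz sampling, default shell parameters). The ODE solve takes
# ~1 s, so it is computed once per test run.
default_burst <- local({
  env <- new.env()
  function() {
    if (is.null(env$b)) env$b <- make_burst()
    env$b
  }
})

default_echo <- local({
  env <- new.env()
  function() {
    if (is.null(env$e)) env$e <- simulate_echo(default_burst())
    env$e
  }
})

# Pure cosine covering an integer number of carrier periods.
cosine_signal <- function(periods = 18, spp = 15, amplitude = 1, fs = 60e6) {
  n <- 0:(periods * spp - 1)
  rf_signal(amplitude * cos(2 * pi * n / spp), fs)
}

# Fraction of spectral energy outside the allowed frequencies (+- 1 bin),
# computed on a window of the valid region covering an integer number of
# fundamental periods.
out_of_band_fraction <- function(yhat, allowed_freqs, fs, period_samples,
                                 valid_from = attr(yhat, "valid_from")) {
  v <- if (is.numeric(yhat)) yhat else yhat$value
  if (is.null(valid_from)) valid_from <- 1L
  v <- v[valid_from:length(v)]
  v <- v[seq_len((length(v) %/% period_samples) * period_samples)]
  sp <- signal_spectrum(v, fs = fs)
  df <- sp$frequency[2] - sp$frequency[1]
  keep <- rep(FALSE, nrow(sp))
  for (f in allowed_freqs) keep <- keep | abs(sp$frequency - f) <= df * 1.0001
  sum(sp$power[!keep]) / sum(sp$power)
}
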