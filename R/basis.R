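#' Hilbert transform and analytic signal
#'
#' `analytic_signal()` computes the discrete analytic signal by the standard
#' one-sided-spectrum method (zero the negative-frequency half of the FFT,
#' double the positive half, inverse-transform); `hilbert_transform()`
#' returns its imaginary part. For a cosine spanning an integer number of
#' periods the result is exact; for other records small edge effects of
#' order 1/L appear.
#'
#' @param x Numeric vector or `rf_signal`.
#' @return `analytic_signal()`: complex vector; `hilbert_transform()`:
#'   numeric vector (the 90-degree phase-shifted companion of `x`).
#' @examples
#' n <- 0:63
#' max(abs(hilbert_transform(cos(2 * pi * n / 8)) - sin(2 * pi * n / 8)))
#' @export
analytic_signal <- function(x) {
  v <- sig_values(x, fs = 1)$value
  L <- length(v)
  h <- numeric(L)
  h[1] <- 1
  if (L %% 2 == 0L) {
    h[L / 2 + 1] <- 1
    if (L > 2) h[2:(L / 2)] <- 2
  } else if (L > 1) {
    h[2:((L + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(v) * h, inverse = TRUE) / L
}

#' @rdname analytic_signal
#' @export
hilbert_transform <- function(x) Im(analytic_signal(x))

new_basis_set <- function(components, alpha, f0, n, kind, fs, time) {
  structure(list(components = components, alpha = alpha, f0 = f0,
                 n = as.integer(n), kind = kind, fs = fs, time = time),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> kind = %s, N = %d, f0 = %g Hz, alpha = [%s], %d samples\n",
              x$kind, x$n, x$f0, paste(format(x$alpha), collapse = ", "),
              length(x$components[[1]])))
  invisible(x)
}

#' @export
as_tibble.basis_set <- function(x, ...) {
  purrr::imap_dfr(x$components, function(v, i) {
    tibble::tibble(time = x$time, component = paste0("psi_", i), value = v)
  })
}

#' Rectangular (period-gated) orthogonal decomposition
#'
#' Splits an excitation at carrier frequency `f0` into `n_components`
#' sub-inputs by gating: component `i` keeps every `N`-th carrier period
#' starting at period `i - 1` and is zero elsewhere. The components have
#' disjoint supports (hence are exactly orthogonal), sum to `x`
#' sample-by-sample with unit coefficients, and are periodic with period
#' `N / f0`, so each carries a spectral component at the subharmonic
#' frequency `f0 / N`. This is the decomposition behind the "MISO1" model.
#'
#' Gating is realized by exact sample-index selection with period boundaries
#' at multiples of `fs / f0` samples starting at the first sample, which
#' requires `fs / f0` to be an integer (no silent rounding).
#'
#' @param x Excitation (`rf_signal` or numeric).
#' @param f0 Carrier frequency in Hz.
#' @param n_components Number of sub-inputs N (>= 1; N = 1 returns the
#'   identity decomposition).
#' @param offset Gate-comb origin offset in samples, for sensitivity
#'   studies; default 0 (aligned to the record start).
#' @param fs Sampling frequency if `x` is numeric.
#' @return A `basis_set` with components `psi_i`, coefficients
#'   `alpha_i = 1`, and metadata (`kind = "rect"`).
#' @examples
#' x <- cos(2 * pi * 4 * (0:59) / 60)
#' b <- decompose_rect(x, f0 = 4, fs = 60, n_components = 2)
#' all(b$components[[1]] + b$components[[2]] == x)
#' @export
decompose_rect <- function(x, f0, n_components = 2, offset = 0, fs = NULL) {
  sv <- sig_values(x, fs)
  if (is.null(sv$fs)) stop("Sampling frequency unknown; supply `fs`.")
  N <- as.integer(n_components)
  if (N < 1L) stop("`n_components` must be >= 1.")
  spp <- sv$fs / f0
  if (abs(spp - round(spp)) > 1e-8 * spp)
    stop(sprintf("fs / f0 = %g is not an integer number of samples per carrier period; resample the signal so that fs is an integer multiple of f0.", spp))
  spp <- round(spp)
  if (spp < 2L) stop("Need at least 2 samples per carrier period.")
  L <- length(sv$value)
  if (N > 1L && L < N * spp)
    stop(sprintf("Signal must cover at least one subharmonic period (N/f0 = %d samples).", N * spp))
  idx0 <- (seq_len(L) - 1L) + offset
  period <- floor(idx0 / spp) %% N
  comps <- lapply(0:(N - 1L), function(i) sv$value * (period == i))
  tt <- (seq_len(L) - 1L) / sv$fs
  new_basis_set(comps, alpha = rep(1, N), f0 = f0, n = N, kind = "rect",
                fs = sv$fs, time = tt)
}

#' Hilbert-quadrature orthogonal decomposition
#'
#' Builds the quadrature basis behind the "MISO2" model:
#' `psi_i(n) = x(n) + (-1)^(i-1) * (x(n) cos(w0 (N-1)/N n Ts) +
#' xh(n) sin(w0 (N-1)/N n Ts))`, where `xh` is the Hilbert transform of `x`
#' and `w0 = 2 pi f0`. The modulation shifts a band-limited excitation down
#' to `f0 / N`, so each component carries both the carrier and the
#' subharmonic line; the alternating sign makes the subharmonic parts of
#' consecutive components antiphase, which is why they cancel in the
#' reconstruction `sum(alpha_i psi_i) = x` (with `alpha_i = 1/2` for N = 2)
#' and why the components are mutually orthogonal over an integer number of
#' subharmonic periods. For a pure cosine `A cos(w0 n Ts)` and N = 2 the
#' components reduce to `A cos(w0 n Ts) +- A cos(w0 n Ts / 2)`.
#'
#' @inheritParams decompose_rect
#' @param n_components N; only N = 2 carries the published coefficients
#'   `alpha = 1/2`. Other values are supported experimentally with
#'   `alpha = 1/N` (exact reconstruction requires N even) and trigger a
#'   warning.
#' @return A `basis_set` with `kind = "hilbert"`.
#' @examples
#' n <- 0:59
#' x <- cos(2 * pi * n / 15)
#' b <- decompose_hilbert(x, f0 = 4e6, fs = 60e6)
#' max(abs(0.5 * b$components[[1]] + 0.5 * b$components[[2]] - x))
#' @export
decompose_hilbert <- function(x, f0, n_components = 2, offset = 0, fs = NULL) {
  sv <- sig_values(x, fs)
  if (is.null(sv$fs)) stop("Sampling frequency unknown; supply `fs`.")
  N <- as.integer(n_components)
  if (N < 1L) stop("`n_components` must be >= 1.")
  L <- length(sv$value)
  tt <- (seq_len(L) - 1L) / sv$fs
  if (N == 1L) {
    return(new_basis_set(list(sv$value), alpha = 1, f0 = f0, n = 1L,
                         kind = "hilbert", fs = sv$fs, time = tt))
  }
  if (N != 2L)
    warning("Hilbert-quadrature basis with N != 2 is experimental: reconstruction coefficients are taken as 1/N, exact only for even N.")
  xh <- hilbert_transform(sv$value)
  w0 <- 2 * pi * f0
  ph <- ((seq_len(L) - 1L) + offset) / sv$fs * w0 * (N - 1) / N
  modterm <- sv$value * cos(ph) + xh * sin(ph)
  comps <- lapply(seq_len(N), function(i) sv$value + (-1)^(i - 1) * modterm)
  new_basis_set(comps, alpha = rep(1 / N, N), f0 = f0, n = N,
                kind = "hilbert", fs = sv$fs, time = tt)
}

#' Reconstruct the excitation from a basis set
#'
#' @param b A `basis_set`.
#' @return Numeric vector `sum_i alpha_i psi_i`.
#' @export
reconstruct <- function(b) {
  stopifnot(inherits(b, "basis_set"))
  Reduce(`+`, purrr::map2(b$alpha, b$components, `*`))
}

#' Pairwise orthogonality report of a basis set
#'
#' Computes every normalized pairwise inner product
#' `|<psi_i, psi_j>| / (||psi_i|| ||psi_j||)` between components and flags
#' the set as failing when the maximum exceeds `tolerance`. Zero-norm
#' components are reported as degenerate rather than divided by zero.
#' Inner products are meaningful over an integer number of subharmonic
#' periods (`N / f0`); the report is computed on the record as given.
#'
#' @param b A `basis_set`.
#' @param tolerance Failure threshold on the normalized inner product.
#' @return A tibble of class `orthogonality_report` with columns `i`, `j`,
#'   `inner_product`, `normalized`, `degenerate`; attributes
#'   `max_normalized`, `tolerance` and `pass`.
#' @export
check_orthogonality <- function(b, tolerance = 1e-6) {
  stopifnot(inherits(b, "basis_set"))
  N <- b$n
  norms <- vapply(b$components, function(v) sqrt(sum(v^2)), numeric(1))
  pairs <- utils::combn(N, 2)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ip <- sum(b$components[[i]] * b$components[[j]])
    degen <- norms[i] == 0 || norms[j] == 0
    tibble::tibble(i = i, j = j, inner_product = ip,
                   normalized = if (degen) NA_real_ else abs(ip) / (norms[i] * norms[j]),
                   degenerate = degen)
  })
  mx <- if (all(is.na(rows$normalized))) NA_real_ else max(rows$normalized, na.rm = TRUE)
  attr(rows, "max_normalized") <- mx
  attr(rows, "tolerance") <- tolerance
  attr(rows, "pass") <- !is.na(mx) && mx <= tolerance
  class(rows) <- c("orthogonality_report", class(rows))
  rows
}

#' @export
print.orthogonality_report <- function(x, ...) {
  cat(sprintf("# orthogonality report: max normalized |<xi,xj>| = %s (tolerance %g) -> %s\n",
              format(attr(x, "max_normalized")), attr(x, "tolerance"),
              if (isTRUE(attr(x, "pass"))) "PASS" else "FAIL"))
  NextMethod()
}
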