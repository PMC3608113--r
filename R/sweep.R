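#' Configuration for an RMSE evaluation sweep
#'
#' Bundles every ingredient of the quantitative evaluation protocol: the
#' transmit burst, the bubble parameters, the memory grid, the output SNR
#' levels, the number of noise realizations, and the model variants to
#' compare. Defaults mirror the study conditions: an 18-cycle 4 MHz burst at
#' 1.2 MPa sampled at 60 MHz, memories up to 19 (sampled on {2, 5, 10, 19}),
#' SNR in {Inf, 20, 15, 10} dB, and 10 noise realizations per SNR.
#'
#' @param memories Integer vector of memory values M.
#' @param snr_db Numeric vector of output SNR levels in dB (`Inf` = no noise).
#' @param n_realizations Noise realizations per SNR level.
#' @param methods Subset of `c("siso", "miso1", "miso2")` (miso1 = gated
#'   rect basis, miso2 = Hilbert-quadrature basis).
#' @param order Volterra order P.
#' @param n_components Number of MISO branches N.
#' @param burst Transmit burst (`rf_signal`), default [make_burst()].
#' @param bubble [bubble_params()] for the echo simulation.
#' @param f0 Carrier frequency; defaults to the burst's `f0` attribute.
#' @param seed Base seed; every noise draw is derived from it, so identical
#'   configs give identical sweep tables.
#' @param rcond Pseudo-inverse cutoff used for all fits.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(memories = c(2, 5, 10, 19),
                              snr_db = c(Inf, 20, 15, 10),
                              n_realizations = 10,
                              methods = c("siso", "miso1", "miso2"),
                              order = 3, n_components = 2,
                              burst = make_burst(), bubble = bubble_params(),
                              f0 = NULL, seed = 1, rcond = 1e-10) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(f0)) f0 <- attr(burst, "f0")
  if (is.null(f0)) stop("Supply `f0` (the burst carries no f0 attribute).")
  stopifnot(all(memories >= 1), n_realizations >= 1)
  structure(list(memories = as.integer(memories), snr_db = snr_db,
                 n_realizations = as.integer(n_realizations),
                 methods = methods, order = as.integer(order),
                 n_components = as.integer(n_components),
                 burst = as_rf_signal(burst), bubble = bubble, f0 = f0,
                 seed = as.integer(seed), rcond = rcond),
            class = "experiment_config")
}

# Internal: cached in-sample least-squares design for one (method, memory).
# Stores the kept left singular vectors of the (column-equilibrated)
# regressor matrix; the in-sample LS prediction is the orthogonal projection
# U U' y, identical to fit-then-predict and independent of the equilibration.
sweep_design <- function(xv, fs, method, f0, n_components, M, order, rcond) {
  X <- switch(method,
    siso = build_regressors(xv, M, order),
    miso1 = , miso2 = {
      kind <- if (method == "miso1") "rect" else "hilbert"
      b <- decompose_input(xv, kind, f0, n_components, offset = 0, fs = fs)
      terms <- volterra_terms(M, order)
      do.call(cbind, lapply(b$components, function(ci)
        regressor_columns(lag_matrix(ci, M), terms)))
    },
    stop("Unknown method: ", method)
  )
  cn <- sqrt(colSums(X^2)); cn[cn == 0] <- 1
  sv <- svd(sweep(X, 2, cn, "/"), nv = 0)
  keep <- sv$d > rcond * sv$d[1] & sv$d > 0
  list(U = sv$u[, keep, drop = FALSE], rank = sum(keep))
}

#' Run the RMSE-versus-memory noise sweep
#'
#' Executes the full evaluation protocol: simulate the microbubble echo once,
#' then for every (SNR, realization) add seeded white Gaussian noise to the
#' output and, for every method and memory, fit the model to the noisy
#' output and record the in-sample relative mean square error (in dB,
#' evaluated over the valid rows `n >= M - 1` against the noisy output --
#' an identification protocol, not a denoising one). The same noise
#' realization is shared across methods and memories so comparisons are
#' paired. Per-cell failures are recorded in the `note` column and the sweep
#' continues.
#'
#' @param config An [experiment_config()].
#' @param x,y Optional excitation/output overrides (both `rf_signal` or
#'   numeric on the burst grid). By default `x` is the configured burst and
#'   `y` is the simulated echo. Supplying them lets the harness evaluate
#'   arbitrary known systems.
#' @param reference `"noisy"` (default) computes the RMSE against the noisy
#'   output that was fitted; `"clean"` computes it against the noiseless
#'   output.
#' @return A tibble of class `rmse_sweep` with columns `method`, `memory`,
#'   `snr_db`, `realization`, `rank`, `rmse`, `rmse_db`, `note`, and the
#'   config as attribute.
#' @seealso [summarize_sweep()], [autoplot.rmse_sweep()]
#' @export
run_sweep <- function(config, x = NULL, y = NULL,
                      reference = c("noisy", "clean")) {
  stopifnot(inherits(config, "experiment_config"))
  reference <- match.arg(reference)
  burst <- config$burst
  fs <- attr(burst, "fs")
  if (is.null(x)) x <- burst
  xv <- sig_values(x, fs)$value
  if (is.null(y)) y <- simulate_echo(burst, config$bubble)
  yv <- sig_values(y, fs)$value
  L <- length(yv)

  grid_mm <- expand.grid(method = config$methods, memory = config$memories,
                         stringsAsFactors = FALSE)
  designs <- vector("list", nrow(grid_mm))
  notes <- character(nrow(grid_mm))
  for (g in seq_len(nrow(grid_mm))) {
    designs[g] <- list(tryCatch(
      sweep_design(xv, fs, grid_mm$method[g], config$f0,
                   config$n_components, grid_mm$memory[g], config$order,
                   config$rcond),
      error = function(e) {notes[g] <<- conditionMessage(e); NULL}))
  }

  cells <- list()
  for (si in seq_along(config$snr_db)) {
    snr <- config$snr_db[si]
    for (ri in seq_len(config$n_realizations)) {
      cell_seed <- (config$seed * 7919 + si * 1009 + ri) %% 2147483647L
      yn <- if (is.infinite(snr)) yv else add_noise(yv, snr, seed = cell_seed)
      yref <- if (reference == "noisy") yn else yv
      for (g in seq_len(nrow(grid_mm))) {
        M <- grid_mm$memory[g]
        d <- designs[[g]]
        row <- tibble::tibble(
          method = grid_mm$method[g], memory = M, snr_db = snr,
          realization = ri, rank = NA_integer_,
          rmse = NA_real_, rmse_db = NA_real_, note = notes[g]
        )
        if (!is.null(d)) {
          ynv <- yn[M:L]
          yrv <- yref[M:L]
          fit <- drop(d$U %*% crossprod(d$U, ynv))
          r <- mean((fit - yrv)^2) / mean(yrv^2)
          row$rank <- d$rank
          row$rmse <- r
          row$rmse_db <- 10 * log10(r)
        }
        cells[[length(cells) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(cells)
  attr(out, "config") <- config
  attr(out, "reference") <- reference
  class(out) <- c("rmse_sweep", class(out))
  out
}

#' Summarize a sweep over noise realizations
#'
#' Mean and standard deviation of the per-realization RMSE (dB) for each
#' (method, memory, SNR) cell.
#'
#' @param sweep The tibble returned by [run_sweep()].
#' @return A tibble with columns `method`, `memory`, `snr_db`,
#'   `mean_rmse_db`, `sd_rmse_db`, `n`.
#' @export
summarize_sweep <- function(sweep) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sweep), .data$method, .data$memory,
                    .data$snr_db),
    mean_rmse_db = mean(.data$rmse_db, na.rm = TRUE),
    sd_rmse_db = stats::sd(.data$rmse_db, na.rm = TRUE),
    n = dplyr::n(), .groups = "drop"
  )
}

#' SISO-to-MISO RMSE gap per SNR level
#'
#' For each SNR level, the difference between the mean SISO RMSE (dB) and
#' the mean RMSE of the *worse* of the two MISO variants at the given
#' memory: a conservative measure of how much the orthogonal decomposition
#' buys over the single-input model.
#'
#' @param sweep A [run_sweep()] result containing `siso` and at least one
#'   MISO method.
#' @param memory Memory at which to evaluate the gap (default: the largest
#'   in the sweep).
#' @return A tibble with columns `snr_db`, `rmse_siso_db`, `rmse_miso_db`
#'   (worse MISO variant), `gap_db`.
#' @export
sweep_gap <- function(sweep, memory = NULL) {
  sm <- summarize_sweep(sweep)
  if (is.null(memory)) memory <- max(sm$memory)
  sm <- sm[sm$memory == memory, ]
  siso <- sm[sm$method == "siso", c("snr_db", "mean_rmse_db")]
  miso <- dplyr::summarise(
    dplyr::group_by(sm[sm$method != "siso", ], .data$snr_db),
    rmse_miso_db = max(.data$mean_rmse_db), .groups = "drop")
  out <- dplyr::inner_join(siso, miso, by = "snr_db")
  names(out)[names(out) == "mean_rmse_db"] <- "rmse_siso_db"
  out$gap_db <- out$rmse_siso_db - out$rmse_miso_db
  out
}
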