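# Internal: decomposition dispatcher shared by fit_miso / predict.
decompose_input <- function(x, kind, f0, n_components, offset, fs = NULL) {
  if (n_components == 1L) {
    sv <- sig_values(x, fs)
    tt <- (seq_along(sv$value) - 1L) / sv$fs
    return(new_basis_set(list(sv$value), alpha = 1, f0 = f0, n = 1L,
                         kind = kind, fs = sv$fs, time = tt))
  }
  switch(kind,
    rect = decompose_rect(x, f0, n_components, offset, fs),
    hilbert = decompose_hilbert(x, f0, n_components, offset, fs),
    stop("Unknown basis kind: ", kind)
  )
}

# Internal: enumeration of cross-branch monomials (degree 2 and 3) over the
# combined lag variables of N branches with memory M. Variables are indexed
# 1..N*M; variable v belongs to branch (v-1) %/% M + 1. Only monomials mixing
# at least two branches are listed (within-branch monomials live in the
# per-branch term tables).
mixed_terms <- function(N, M, order) {
  if (order < 2L || N < 2L) {
    return(tibble::tibble(v1 = integer(), v2 = integer(), v3 = integer()))
  }
  V <- N * M
  br <- function(v) (v - 1L) %/% M + 1L
  g2 <- expand.grid(v2 = seq_len(V), v1 = seq_len(V))
  g2 <- g2[g2$v1 <= g2$v2 & br(g2$v1) != br(g2$v2), c("v1", "v2")]
  g2 <- g2[order(g2$v1, g2$v2), ]
  out <- tibble::tibble(v1 = g2$v1, v2 = g2$v2, v3 = NA_integer_)
  if (order >= 3L) {
    g3 <- expand.grid(v3 = seq_len(V), v2 = seq_len(V), v1 = seq_len(V))
    g3 <- g3[g3$v1 <= g3$v2 & g3$v2 <= g3$v3, ]
    mixed <- !(br(g3$v1) == br(g3$v2) & br(g3$v2) == br(g3$v3))
    g3 <- g3[mixed, c("v1", "v2", "v3")]
    g3 <- g3[order(g3$v1, g3$v2, g3$v3), ]
    out <- dplyr::bind_rows(out, tibble::tibble(v1 = g3$v1, v2 = g3$v2, v3 = g3$v3))
  }
  out
}

mixed_columns <- function(lag_all, terms) {
  out <- matrix(1, nrow(lag_all), nrow(terms))
  for (j in seq_len(nrow(terms))) {
    for (vc in c("v1", "v2", "v3")) {
      v <- terms[[vc]][j]
      if (!is.na(v)) out[, j] <- out[, j] * lag_all[, v]
    }
  }
  out
}

#' Fit a MISO Volterra model on an orthogonally decomposed excitation
#'
#' Splits the excitation into `n_components` periodic orthogonal sub-inputs
#' (see [decompose_rect()] and [decompose_hilbert()]), builds per-branch
#' Volterra regressors -- the model is N parallel SISO branches sharing the
#' order and memory, with no cross-branch product terms by default -- and
#' estimates all branch kernels by least squares against the common output.
#' Because each sub-input carries a spectral line at `f0 / N`, the branch
#' kernels can generate sub- and ultraharmonics (`f0/2`, `3 f0/2`, ...)
#' that a SISO Volterra model of any order cannot represent.
#'
#' `fit_mode = "joint"` (default) solves one least-squares problem over the
#' concatenated branch regressors; `"parallel"` fits each branch
#' independently against `y`. The two coincide exactly when the branch
#' regressors are mutually orthogonal; with the gated (rect) basis, memory
#' spill-over of up to M - 1 samples at gate boundaries breaks orthogonality
#' slightly, making the joint solve the exact least-squares answer.
#'
#' @param x Excitation signal (`rf_signal` or numeric).
#' @param y Measured output, same length and grid as `x`.
#' @param basis `"rect"` (MISO1) or `"hilbert"` (MISO2).
#' @param f0 Carrier frequency of the excitation in Hz.
#' @param n_components Number of branches N (default 2, the subharmonic
#'   case; N = 1 reduces exactly to [fit_siso()]).
#' @param memory,order Shared memory M and order P of every branch.
#' @param fit_mode `"joint"` or `"parallel"`.
#' @param cross_terms If `TRUE`, augment the joint model with cross-branch
#'   product regressors (products mixing lags of different sub-inputs).
#'   Off by default: the parallel-branch structure is the model studied
#'   here; the switch exists for research comparisons.
#' @param offset Decomposition phase-origin offset in samples.
#' @param rcond,ridge Passed to the least-squares solver (see [fit_siso()]).
#' @param fs Sampling frequency if `x`/`y` are numeric.
#' @return An object of class `miso_volterra`: `basis` (the fitted
#'   decomposition), `branches` (list of [volterra_kernels()]), optional
#'   `cross` coefficients, `fitted`, `rank`, `rmse`, `rmse_db`.
#' @export
fit_miso <- function(x, y, basis = c("rect", "hilbert"), f0,
                     n_components = 2, memory, order = 3,
                     fit_mode = c("joint", "parallel"),
                     cross_terms = FALSE, offset = 0,
                     rcond = 1e-10, ridge = 0, fs = NULL) {
  basis <- match.arg(basis)
  fit_mode <- match.arg(fit_mode)
  xs <- sig_values(x, fs)
  ys <- sig_values(y, fs = xs$fs)
  if (length(xs$value) != length(ys$value))
    stop("`x` and `y` must have the same length.")
  M <- as.integer(memory)
  N <- as.integer(n_components)
  b <- decompose_input(xs$value, basis, f0, N, offset, fs = xs$fs)
  L <- length(xs$value)
  yv <- ys$value[M:L]
  terms <- volterra_terms(M, order)
  lag_mats <- lapply(b$components, lag_matrix, M = M)
  Xb <- lapply(lag_mats, regressor_columns, terms = terms)
  npar <- nrow(terms)

  cross <- NULL
  if (fit_mode == "joint") {
    X <- do.call(cbind, Xb)
    if (cross_terms && N >= 2L) {
      ct <- mixed_terms(N, M, order)
      if (nrow(ct) > 0) {
        Xc <- mixed_columns(do.call(cbind, lag_mats), ct)
        X <- cbind(X, Xc)
      }
    }
    sol <- ls_solve(X, yv, rcond = rcond, ridge = ridge)
    branches <- lapply(seq_len(N), function(i) {
      volterra_kernels(sol$coef[(i - 1) * npar + seq_len(npar)], M, order)
    })
    if (cross_terms && N >= 2L && nrow(ct <- mixed_terms(N, M, order)) > 0) {
      cross <- list(terms = ct, coef = sol$coef[N * npar + seq_len(nrow(ct))])
    }
    rank <- sol$rank
  } else {
    if (cross_terms)
      warning("`cross_terms` is ignored in parallel fit mode.")
    sols <- lapply(Xb, ls_solve, y = yv, rcond = rcond, ridge = ridge)
    branches <- lapply(sols, function(s) volterra_kernels(s$coef, M, order))
    rank <- sum(vapply(sols, `[[`, numeric(1), "rank"))
  }

  fit <- structure(list(
    basis = b, branches = branches, cross = cross,
    fit_mode = fit_mode, memory = M, order = as.integer(order),
    n_components = N, f0 = f0, offset = offset, rank = rank,
    nobs = length(yv), rcond = rcond, ridge = ridge,
    x = as_rf_signal(xs$value, if (is.null(xs$fs)) 1 else xs$fs)
  ), class = "miso_volterra")
  fit$fitted <- predict(fit, x)
  fit$rmse <- if (all(yv == 0)) NA_real_ else
    rmse(ys$value, fit$fitted$value, valid_from = M)
  fit$rmse_db <- 10 * log10(fit$rmse)
  fit
}

#' @export
print.miso_volterra <- function(x, ...) {
  cat(sprintf("<miso_volterra> basis = %s, N = %d, P = %d, M = %d (%s fit, rank %d)\n",
              x$basis$kind, x$n_components, x$order, x$memory,
              x$fit_mode, x$rank))
  if (!is.null(x$rmse_db))
    cat(sprintf("  in-sample RMSE = %.2f dB\n", x$rmse_db))
  invisible(x)
}

#' Predict from a MISO Volterra model
#'
#' Decomposes the excitation with the model's stored basis, evaluates every
#' branch, and returns the summed prediction. The per-branch outputs
#' `yhat_i` (with `yhat = sum_i yhat_i`, plus a cross-term contribution when
#' the model was fitted with `cross_terms = TRUE`) are attached as the
#' `branches` attribute and can be retrieved in long form with
#' [miso_branches()].
#'
#' @param object A `miso_volterra` fit.
#' @param newdata New excitation (`rf_signal` or numeric); default: the
#'   training excitation.
#' @param ... Unused.
#' @return An `rf_signal` with attributes `valid_from` and `branches`.
#' @export
predict.miso_volterra <- function(object, newdata = NULL, ...) {
  if (is.null(newdata) && !is.null(object$fitted)) return(object$fitted)
  x <- if (is.null(newdata)) object$x else newdata
  sv <- sig_values(x, fs = attr(object$x, "fs"))
  b <- decompose_input(sv$value, object$basis$kind, object$f0,
                       object$n_components, object$offset, fs = sv$fs)
  M <- object$memory
  L <- length(sv$value)
  lag_mats <- lapply(b$components, lag_matrix, M = M)
  branch_sigs <- purrr::map2(lag_mats, object$branches, function(lm, k) {
    v <- numeric(L)
    v[M:L] <- drop(regressor_columns(lm, k$terms) %*% k$coef)
    s <- rf_signal(v, sv$fs)
    attr(s, "valid_from") <- M
    s
  })
  names(branch_sigs) <- paste0("branch_", seq_along(branch_sigs))
  total <- Reduce(`+`, lapply(branch_sigs, function(s) s$value))
  if (!is.null(object$cross)) {
    vc <- numeric(L)
    vc[M:L] <- drop(mixed_columns(do.call(cbind, lag_mats),
                                  object$cross$terms) %*% object$cross$coef)
    total <- total + vc
  }
  out <- rf_signal(total, sv$fs)
  attr(out, "valid_from") <- M
  attr(out, "branches") <- branch_sigs
  out
}

#' @rdname predict.miso_volterra
#' @param prediction An `rf_signal` returned by `predict.miso_volterra`.
#' @export
miso_branches <- function(prediction) {
  br <- attr(prediction, "branches")
  if (is.null(br)) stop("No branch outputs attached to this prediction.")
  purrr::imap_dfr(br, function(s, nm) {
    tibble::tibble(time = s$time, branch = nm, value = s$value)
  })
}

#' @export
tidy.miso_volterra <- function(x, ...) {
  purrr::imap_dfr(x$branches, function(k, i) {
    dplyr::mutate(tidy(k), branch = paste0("branch_", i), .before = 1)
  })
}

#' @export
glance.miso_volterra <- function(x, ...) {
  tibble::tibble(basis = x$basis$kind, n_components = x$n_components,
                 memory = x$memory, order = x$order,
                 fit_mode = x$fit_mode,
                 n_params = x$n_components * length(x$branches[[1]]$coef) +
                   if (is.null(x$cross)) 0L else length(x$cross$coef),
                 rank = x$rank, nobs = x$nobs,
                 rmse = x$rmse, rmse_db = x$rmse_db)
}
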