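#' Term table of a Volterra model
#'
#' Enumerates the model terms of a discrete Volterra expansion of order
#' `order` and memory `memory` in symmetric-unique form: one constant term,
#' the `M` linear lags, the `M(M+1)/2` unique quadratic lag pairs
#' (`k1 <= k2`) and the `M(M+1)(M+2)/6` unique cubic triples
#' (`k1 <= k2 <= k3`), in lexicographic lag order. This fixes the column
#' order of the regressor matrix and the storage order of estimated kernels.
#' The symmetric-unique parameterization avoids the rank deficiency of the
#' full product enumeration (lag products are invariant under permutation of
#' their lags); expansion to full symmetric tensors is available via
#' [expand_kernels()].
#'
#' @param memory Memory M (number of lags per kernel dimension), >= 1.
#' @param order Model order P, between 1 and 3.
#' @return A tibble with columns `term` (label such as `"h2(0,1)"`),
#'   `order`, and integer lags `k1`, `k2`, `k3` (`NA` where unused).
#' @examples
#' nrow(volterra_terms(2, 3)) # 1 + 2 + 3 + 4 = 10
#' @export
volterra_terms <- function(memory, order = 3) {
  M <- as.integer(memory); P <- as.integer(order)
  if (M < 1L) stop("`memory` must be >= 1.")
  if (P < 1L || P > 3L) stop("`order` must be 1, 2 or 3.")
  rows <- list(tibble::tibble(term = "h0", order = 0L,
                              k1 = NA_integer_, k2 = NA_integer_, k3 = NA_integer_))
  k <- 0:(M - 1L)
  rows[[2]] <- tibble::tibble(term = sprintf("h1(%d)", k), order = 1L,
                              k1 = k, k2 = NA_integer_, k3 = NA_integer_)
  if (P >= 2L) {
    g <- expand.grid(k2 = k, k1 = k)
    g <- g[g$k1 <= g$k2, c("k1", "k2")]
    g <- g[order(g$k1, g$k2), ]
    rows[[3]] <- tibble::tibble(term = sprintf("h2(%d,%d)", g$k1, g$k2),
                                order = 2L, k1 = g$k1, k2 = g$k2,
                                k3 = NA_integer_)
  }
  if (P >= 3L) {
    g <- expand.grid(k3 = k, k2 = k, k1 = k)
    g <- g[g$k1 <= g$k2 & g$k2 <= g$k3, c("k1", "k2", "k3")]
    g <- g[order(g$k1, g$k2, g$k3), ]
    rows[[4]] <- tibble::tibble(term = sprintf("h3(%d,%d,%d)", g$k1, g$k2, g$k3),
                                order = 3L, k1 = g$k1, k2 = g$k2, k3 = g$k3)
  }
  dplyr::bind_rows(rows)
}

# Internal: lag matrix with columns x(n-k), k = 0..M-1, rows n = M-1..L-1
# (0-based), i.e. R rows M..L.
lag_matrix <- function(x, M) {
  L <- length(x)
  n <- M:L
  vapply(0:(M - 1L), function(k) x[n - k], numeric(length(n)))
}

# Internal: regressor columns from a lag matrix and a term table whose
# k1/k2/k3 columns index into `lags` (1-based column index, NA = unused).
regressor_columns <- function(lags, terms) {
  out <- matrix(1, nrow(lags), nrow(terms))
  for (j in seq_len(nrow(terms))) {
    for (kc in c("k1", "k2", "k3")) {
      k <- terms[[kc]][j]
      if (!is.na(k)) out[, j] <- out[, j] * lags[, k + 1L]
    }
  }
  out
}

#' Build the Volterra regressor matrix
#'
#' One row per valid time index `n` in `[M-1, L-1]` (0-based; `L - M + 1`
#' rows), one column per term of [volterra_terms()]: the constant, the lagged
#' inputs `x(n-k)`, and the unique quadratic and cubic lag products.
#'
#' @param x Input signal (`rf_signal` or numeric).
#' @param memory Memory M; the signal must contain at least `M` samples.
#' @param order Model order P (1-3).
#' @return A numeric matrix with attributes `terms` (the term table) and
#'   `valid_from` (1-based index of the first modeled output sample, `= M`).
#' @examples
#' build_regressors(c(1, 2, 3), memory = 2, order = 2)
#' @export
build_regressors <- function(x, memory, order = 3) {
  v <- sig_values(x, fs = 1)$value
  M <- as.integer(memory)
  if (length(v) < M)
    stop(sprintf("Signal of length %d is shorter than memory M = %d; need at least %d samples.",
                 length(v), M, M))
  terms <- volterra_terms(M, order)
  X <- regressor_columns(lag_matrix(v, M), terms)
  colnames(X) <- terms$term
  attr(X, "terms") <- terms
  attr(X, "valid_from") <- M
  X
}

# Internal: rank-revealing least squares via SVD pseudo-inverse with column
# equilibration (unit-norm columns) so the relative singular-value cutoff is
# meaningful when regressor blocks differ by orders of magnitude (e.g. a
# drive in Pa makes cubic columns ~1e18 times the constant column).
# Equilibration does not change the column space, hence fitted values are
# unaffected. Returns coefficients on the original scale.
ls_solve <- function(X, y, rcond = 1e-10, ridge = 0) {
  cn <- sqrt(colSums(X^2))
  zero <- cn == 0
  cn[zero] <- 1
  Xs <- sweep(X, 2, cn, "/")
  sv <- svd(Xs)
  keep <- sv$d > rcond * sv$d[1] & sv$d > 0
  dk <- sv$d[keep]
  uty <- crossprod(sv$u[, keep, drop = FALSE], y)
  f <- if (ridge > 0) dk / (dk^2 + ridge) else 1 / dk
  beta <- drop(sv$v[, keep, drop = FALSE] %*% (f * uty)) / cn
  beta[zero] <- 0
  list(coef = beta, rank = sum(keep), singular_values = sv$d)
}

#' Volterra kernel set
#'
#' Container for an estimated (or hand-specified) kernel set
#' `{h0, h1, h2, h3}` of order `order` and memory `memory`, stored in
#' symmetric-unique form in the column order of [volterra_terms()].
#'
#' @param coef Numeric vector of kernel coefficients, one per term.
#' @param memory Memory M.
#' @param order Order P (1-3).
#' @return An object of class `volterra_kernels`.
#' @export
volterra_kernels <- function(coef, memory, order = 3) {
  terms <- volterra_terms(memory, order)
  coef <- as.numeric(coef)
  if (length(coef) != nrow(terms))
    stop(sprintf("Expected %d coefficients for memory %d, order %d; got %d.",
                 nrow(terms), memory, order, length(coef)))
  structure(list(coef = coef, terms = terms,
                 memory = as.integer(memory), order = as.integer(order)),
            class = "volterra_kernels")
}

#' @export
print.volterra_kernels <- function(x, ...) {
  cat(sprintf("<volterra_kernels> order P = %d, memory M = %d, %d parameters\n",
              x$order, x$memory, length(x$coef)))
  invisible(x)
}

#' Random Volterra kernels
#'
#' Draws i.i.d. Gaussian kernel coefficients; handy for constructing known
#' synthetic systems in simulations and tests.
#'
#' @param memory Memory M.
#' @param order Order P.
#' @param sd Standard deviation of the coefficients.
#' @param seed Optional seed (caller's RNG state is preserved).
#' @return A `volterra_kernels` object.
#' @export
random_kernels <- function(memory, order = 3, sd = 1, seed = NULL) {
  n <- nrow(volterra_terms(memory, order))
  draw <- function() stats::rnorm(n, 0, sd)
  coef <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  volterra_kernels(coef, memory, order)
}

#' Expand kernels to full symmetric tensors
#'
#' Converts the symmetric-unique storage into the full symmetric
#' representation: `h1` a length-M vector, `h2` an M x M symmetric matrix,
#' `h3` an M x M x M symmetric array. Each unique coefficient is divided
#' equally among the distinct permutations of its lag multiset, so that the
#' full-tensor sums reproduce the model output exactly.
#'
#' @param k A `volterra_kernels` object.
#' @return A list with elements `h0`, `h1`, and (as applicable) `h2`, `h3`.
#' @export
expand_kernels <- function(k) {
  stopifnot(inherits(k, "volterra_kernels"))
  M <- k$memory
  out <- list(h0 = k$coef[k$terms$order == 0L],
              h1 = k$coef[k$terms$order == 1L])
  if (k$order >= 2L) {
    h2 <- matrix(0, M, M)
    t2 <- k$terms[k$terms$order == 2L, ]
    c2 <- k$coef[k$terms$order == 2L]
    for (j in seq_len(nrow(t2))) {
      i1 <- t2$k1[j] + 1L; i2 <- t2$k2[j] + 1L
      if (i1 == i2) h2[i1, i1] <- c2[j]
      else { h2[i1, i2] <- c2[j] / 2; h2[i2, i1] <- c2[j] / 2 }
    }
    out$h2 <- h2
  }
  if (k$order >= 3L) {
    h3 <- array(0, c(M, M, M))
    t3 <- k$terms[k$terms$order == 3L, ]
    c3 <- k$coef[k$terms$order == 3L]
    for (j in seq_len(nrow(t3))) {
      ks <- c(t3$k1[j], t3$k2[j], t3$k3[j]) + 1L
      perms <- unique(list(ks[c(1, 2, 3)], ks[c(1, 3, 2)], ks[c(2, 1, 3)],
                           ks[c(2, 3, 1)], ks[c(3, 1, 2)], ks[c(3, 2, 1)]))
      for (pp in perms) h3[pp[1], pp[2], pp[3]] <- c3[j] / length(perms)
    }
    out$h3 <- h3
  }
  out
}

#' @export
predict.volterra_kernels <- function(object, x, ...) {
  sv <- sig_values(x, fs = 1)
  X <- build_regressors(sv$value, object$memory, object$order)
  M <- object$memory
  yhat <- numeric(length(sv$value))
  yhat[M:length(sv$value)] <- drop(X %*% object$coef)
  out <- if (is.numeric(x)) rf_signal(yhat, fs = if (is.null(sv$fs)) 1 else sv$fs)
         else { s <- as_rf_signal(x); s$value <- yhat; s }
  attr(out, "valid_from") <- M
  out
}

#' Fit a SISO Volterra model by least squares
#'
#' Estimates the kernel set minimizing the mean squared error between the
#' measured output and the model output over the valid rows
#' `n in [M-1, L-1]`, via the normal-equations solution computed with a
#' rank-revealing SVD pseudo-inverse (relative singular-value cutoff
#' `rcond`; optional ridge penalty). When the regressor matrix is
#' rank-deficient -- as it always is for a pure-tone input, whose lagged
#' products span only the lines {0, f0, 2 f0, 3 f0} -- the minimum-norm
#' solution is returned.
#'
#' @param x Input signal (`rf_signal` or numeric).
#' @param y Output signal, same length (and grid) as `x`.
#' @param memory Memory M.
#' @param order Order P (1-3), default 3.
#' @param rcond Relative singular-value cutoff of the pseudo-inverse.
#' @param ridge Optional ridge (Tikhonov) parameter, default 0.
#' @return An object of class `siso_volterra` with elements `kernels`
#'   (a [volterra_kernels()] object), `fitted` (`rf_signal`), `rank`,
#'   `singular_values`, `rmse`, `rmse_db`, `nobs`.
#' @examples
#' x <- rnorm(200)
#' y <- 2 * x
#' fit <- fit_siso(x, y, memory = 3, order = 3)
#' tidy(fit)$estimate[2] # h1(0) = 2
#' @export
fit_siso <- function(x, y, memory, order = 3, rcond = 1e-10, ridge = 0) {
  xs <- sig_values(x, fs = 1)
  ys <- sig_values(y, fs = xs$fs)
  if (length(xs$value) != length(ys$value))
    stop("`x` and `y` must have the same length.")
  if (all(xs$value == 0) && any(ys$value != 0))
    warning("Input is identically zero; only the constant term h0 = mean(y) is identifiable, the remaining residual is irreducible.")
  M <- as.integer(memory)
  X <- build_regressors(xs$value, M, order)
  yv <- ys$value[M:length(ys$value)]
  sol <- ls_solve(X, yv, rcond = rcond, ridge = ridge)
  kernels <- volterra_kernels(sol$coef, M, order)
  fitted <- predict(kernels, x)
  structure(list(
    kernels = kernels, memory = M, order = as.integer(order),
    rank = sol$rank, singular_values = sol$singular_values,
    fitted = fitted, nobs = length(yv),
    rmse = if (all(yv == 0)) NA_real_ else rmse(y, fitted, valid_from = M),
    rmse_db = if (all(yv == 0)) NA_real_ else rmse_db(y, fitted, valid_from = M),
    x = as_rf_signal(xs$value, if (is.null(xs$fs)) 1 else xs$fs),
    rcond = rcond, ridge = ridge
  ), class = "siso_volterra")
}

#' @export
print.siso_volterra <- function(x, ...) {
  cat(sprintf("<siso_volterra> P = %d, M = %d (%d params, rank %d), in-sample RMSE = %.2f dB\n",
              x$order, x$memory, length(x$kernels$coef), x$rank, x$rmse_db))
  invisible(x)
}

#' @export
predict.siso_volterra <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict(object$kernels, newdata)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.volterra_kernels <- function(x, ...) {
  dplyr::mutate(x$terms, estimate = x$coef)
}

#' @export
tidy.siso_volterra <- function(x, ...) tidy(x$kernels)

#' @export
glance.siso_volterra <- function(x, ...) {
  tibble::tibble(memory = x$memory, order = x$order,
                 n_params = length(x$kernels$coef), rank = x$rank,
                 nobs = x$nobs, rmse = x$rmse, rmse_db = x$rmse_db)
}

#' Serialize kernels to JSON / TSV
#'
#' `write_kernels()` stores order, memory, term order and coefficients in a
#' portable JSON file; `read_kernels()` restores the object.
#' `write_kernels_tsv()` writes the tidy one-row-per-term table as
#' tab-separated text.
#'
#' @param k A `volterra_kernels` object.
#' @param path Output file path.
#' @return `read_kernels` returns a `volterra_kernels`; the writers return
#'   `path` invisibly.
#' @export
write_kernels <- function(k, path) {
  stopifnot(inherits(k, "volterra_kernels"))
  jsonlite::write_json(
    list(order = k$order, memory = k$memory,
         term = k$terms$term, coef = k$coef),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kernels
#' @export
read_kernels <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- volterra_kernels(obj$coef, obj$memory, obj$order)
  if (!identical(k$terms$term, as.character(obj$term)))
    stop("Term order in file does not match this package's column order.")
  k
}

#' @rdname write_kernels
#' @export
write_kernels_tsv <- function(k, path) {
  utils::write.table(as.data.frame(tidy(k)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
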