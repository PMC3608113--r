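test_that("term enumeration has the closed-form parameter count", {
  for (M in c(1, 2, 5, 19)) {
    for (P in 1:3) {
      n_expected <- 1 + M +
        (if (P >= 2) M * (M + 1) / 2 else 0) +
        (if (P >= 3) M * (M + 1) * (M + 2) / 6 else 0)
      expect_equal(nrow(volterra_terms(M, P)), n_expected)
    }
  }
  expect_equal(nrow(volterra_terms(2, 3)), 10)
})

test_that("regressor rows enumerate the unique lag products", {
  # hand enumeration: x = [1,2,3], M = 2, P = 2; row for n = 1 (0-based) is
  # {1, x(1), x(0), x(1)^2, x(1)x(0), x(0)^2}
  X <- build_regressors(c(1, 2, 3), memory = 2, order = 2)
  expect_equal(nrow(X), 2)  # n = 1, 2
  expect_equal(unname(X[1, ]), c(1, 2, 1, 4, 2, 1))
  expect_equal(unname(X[2, ]), c(1, 3, 2, 9, 6, 4))
  expect_equal(attr(X, "valid_from"), 2)

  expect_true(all(build_regressors(rep(1, 10), 3, 3) == 1))
  expect_error(build_regressors(c(1, 2), memory = 5), "at least 5 samples")
})

test_that("noiseless kernel recovery is exact at full column rank", {
  k <- random_kernels(memory = 3, order = 3, seed = 11)
  x <- withr::with_seed(21, rnorm(500))
  y <- predict(k, x)
  fit <- fit_siso(x, y, memory = 3, order = 3)
  rel <- max(abs(fit$kernels$coef - k$coef)) / max(abs(k$coef))
  expect_lt(rel, 1e-8)
  expect_equal(fit$rank, length(k$coef))
})

test_that("simple systems land on the expected kernels", {
  x <- withr::with_seed(3, rnorm(300))
  fit2x <- fit_siso(x, 2 * x, memory = 3)
  td <- tidy(fit2x)
  expect_equal(td$estimate[td$term == "h1(0)"], 2, tolerance = 1e-10)
  expect_lt(max(abs(td$estimate[td$term != "h1(0)"])), 1e-10)

  fitsq <- fit_siso(x, x^2, memory = 3)
  td <- tidy(fitsq)
  expect_equal(td$estimate[td$term == "h2(0,0)"], 1, tolerance = 1e-10)
  expect_lt(max(abs(td$estimate[td$term != "h2(0,0)"])), 1e-10)
})

test_that("all-zero input warns and falls back to the output mean", {
  y <- withr::with_seed(5, rnorm(100)) + 3
  expect_warning(fit <- fit_siso(rep(0, 100), y, memory = 2), "identically zero")
  expect_equal(tidy(fit)$estimate[1], mean(y[2:100]), tolerance = 1e-10)
})

test_that("the LS residual is orthogonal to every regressor column", {
  x <- withr::with_seed(8, rnorm(400))
  y <- withr::with_seed(9, rnorm(400))
  M <- 4
  fit <- fit_siso(x, y, memory = M)
  X <- build_regressors(x, M)
  r <- y[M:400] - fit$fitted$value[M:400]
  g <- crossprod(X, r)
  expect_lt(max(abs(g)) / (max(abs(crossprod(X, y[M:400]))) + 1), 1e-8)
})

test_that("kernels scale linearly with the output", {
  x <- withr::with_seed(13, rnorm(250))
  y <- withr::with_seed(14, rnorm(250))
  f1 <- fit_siso(x, y, memory = 3)
  f5 <- fit_siso(x, 5 * y, memory = 3)
  expect_equal(f5$kernels$coef, 5 * f1$kernels$coef, tolerance = 1e-8)
})

test_that("a single-tone input can only excite 0, f0, 2f0 and 3f0", {
  # spectral closure: the third-order SISO model class is spanned by lagged
  # cosine products, whose spectra live exactly on integer multiples of f0
  spp <- 16
  x <- cos(2 * pi * (0:(spp * 40 + 9)) / spp)
  k <- random_kernels(memory = 6, order = 3, seed = 31)
  yhat <- predict(k, x)
  frac <- out_of_band_fraction(yhat, allowed_freqs = c(0, 1, 2, 3) / spp,
                               fs = 1, period_samples = spp)
  expect_lt(frac, 1e-10)

  # ...and a fitted model inherits the same support
  fit <- fit_siso(x, withr::with_seed(4, rnorm(length(x))), memory = 6)
  frac_fit <- out_of_band_fraction(fit$fitted, allowed_freqs = c(0, 1, 2, 3) / spp,
                                   fs = 1, period_samples = spp)
  expect_lt(frac_fit, 1e-10)
})

test_that("prediction is flagged invalid before the first full lag window", {
  k <- volterra_kernels(c(7, rep(0, 9)), memory = 2, order = 3)  # h0 = 7 only
  yhat <- predict(k, rnorm(50))
  expect_equal(attr(yhat, "valid_from"), 2)
  expect_equal(yhat$value[1], 0)
  expect_true(all(yhat$value[2:50] == 7))
})

test_that("expanded symmetric tensors reproduce the model output", {
  M <- 3
  k <- random_kernels(M, 3, seed = 17)
  x <- withr::with_seed(18, rnorm(60))
  full <- expand_kernels(k)
  expect_equal(full$h2, t(full$h2))
  # brute-force evaluation with the full tensors over all lag tuples
  L <- length(x)
  yref <- numeric(L)
  for (n in M:L) {
    lag <- x[n - 0:(M - 1)]
    yref[n] <- full$h0 + sum(full$h1 * lag) +
      sum(full$h2 * outer(lag, lag)) +
      sum(full$h3 * outer(outer(lag, lag), lag))
  }
  yhat <- predict(k, x)
  expect_equal(yhat$value[M:L], yref[M:L], tolerance = 1e-10)
})

test_that("kernel serialization round-trips through JSON and TSV", {
  k <- random_kernels(3, 3, seed = 23)
  path <- withr::local_tempfile(fileext = ".json")
  write_kernels(k, path)
  k2 <- read_kernels(path)
  expect_equal(k2$coef, k$coef, tolerance = 1e-12)
  expect_equal(k2$memory, k$memory)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_kernels_tsv(k, tsv)
  df <- read.delim(tsv)
  expect_equal(nrow(df), length(k$coef))
  expect_equal(df$estimate, k$coef, tolerance = 1e-12)
})
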