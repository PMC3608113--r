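# A known two-branch parallel Volterra system on the gated decomposition of
# a broadband input. The joint MISO design carries one constant column per
# branch, so only the *total* constant is identifiable; the fixture offers
# two flavors:
#   center = FALSE: both branch h0 set to zero (all coefficients, including
#     the vanishing constants, are then uniquely recoverable);
#   center = TRUE: each branch's h0 absorbs minus its output mean, making
#     the branch outputs zero-mean so the branch regressor spaces are
#     mutually orthogonal including the constant direction (used to compare
#     joint and parallel fits).
make_parallel_system <- function(L = 600, M = 3, spp = 8, seed = 101,
                                 center = FALSE) {
  x <- withr::with_seed(seed, rnorm(L))
  b <- decompose_rect(x, f0 = 1 / spp, fs = 1)
  ks <- lapply(1:2, function(i) random_kernels(M, 3, seed = seed + i))
  outs <- vector("list", 2)
  for (i in 1:2) {
    ks[[i]]$coef[1] <- 0
    outs[[i]] <- predict(ks[[i]], b$components[[i]])$value
    if (center) {
      mu <- mean(outs[[i]][M:L])
      ks[[i]]$coef[1] <- -mu
      outs[[i]][M:L] <- outs[[i]][M:L] - mu
    }
  }
  list(x = x, y = outs[[1]] + outs[[2]], kernels = ks, M = M, spp = spp)
}

test_that("joint fit recovers two known orthogonal-branch kernel sets", {
  sys <- make_parallel_system()
  fit <- fit_miso(sys$x, sys$y, basis = "rect", f0 = 1 / sys$spp,
                  memory = sys$M, order = 3, fs = 1)
  for (i in 1:2) {
    rel <- max(abs(fit$branches[[i]]$coef - sys$kernels[[i]]$coef)) /
      max(abs(sys$kernels[[i]]$coef))
    expect_lt(rel, 1e-8)
  }
  expect_lt(fit$rmse, 1e-16)
})

test_that("joint and parallel fits agree when branch regressors are orthogonal", {
  # exact case: gated cosine input (every component sums to zero over its
  # whole carrier periods, as do its odd powers), M = 1 (no memory
  # spill-over) and odd-order-only kernels, so each branch output is
  # exactly orthogonal to the other branch's entire regressor span
  spp <- 8
  x <- cos(2 * pi * (0:(24 * spp - 1)) / spp)
  bset <- decompose_rect(x, f0 = 1 / spp, fs = 1)
  ks <- lapply(1:2, function(i) {
    k <- random_kernels(1, 3, seed = 70 + i)
    k$coef[c(1, 3)] <- 0                       # h0 = h2 = 0: odd orders only
    k
  })
  y <- predict(ks[[1]], bset$components[[1]])$value +
    predict(ks[[2]], bset$components[[2]])$value
  fj <- fit_miso(x, y, "rect", f0 = 1 / spp, memory = 1, fs = 1)
  fp <- fit_miso(x, y, "rect", f0 = 1 / spp, memory = 1,
                 fit_mode = "parallel", fs = 1)
  expect_equal(fp$fitted$value, fj$fitted$value, tolerance = 1e-8)
  expect_lt(fp$rmse, 1e-15)

  # with memory, the spill-over makes the joint solve the better LS answer
  sys3 <- make_parallel_system(M = 3, center = TRUE)
  fj3 <- fit_miso(sys3$x, sys3$y, "rect", f0 = 1 / sys3$spp, memory = 3, fs = 1)
  fp3 <- fit_miso(sys3$x, sys3$y, "rect", f0 = 1 / sys3$spp, memory = 3,
                  fit_mode = "parallel", fs = 1)
  expect_lte(fj3$rmse, fp3$rmse + 1e-12)
})

test_that("a single branch reduces exactly to the SISO fit", {
  x <- withr::with_seed(33, rnorm(300))
  y <- withr::with_seed(34, rnorm(300))
  fm <- fit_miso(x, y, "rect", f0 = 0.125, n_components = 1, memory = 3, fs = 1)
  fsiso <- fit_siso(x, y, memory = 3)
  expect_equal(fm$branches[[1]]$coef, fsiso$kernels$coef, tolerance = 1e-10)
  expect_equal(fm$fitted$value, fsiso$fitted$value, tolerance = 1e-10)
})

test_that("a degenerate decomposition (x2 = 0) reproduces the SISO solution", {
  spp <- 8
  x <- withr::with_seed(55, rnorm(400))
  gate2 <- (floor((seq_along(x) - 1) / spp) %% 2) == 1
  x[gate2] <- 0                      # excitation lives only on gate-1 periods
  y <- withr::with_seed(56, rnorm(400))
  fm <- fit_miso(x, y, "rect", f0 = 1 / spp, memory = 3, fs = 1)
  fsiso <- fit_siso(x, y, memory = 3)
  # the constant is shared between the two branch h0 columns (only their sum
  # is identified); every other branch-2 column is zero and every branch-1
  # column equals the SISO column
  expect_equal(fm$branches[[1]]$coef[-1], fsiso$kernels$coef[-1],
               tolerance = 1e-8)
  expect_equal(fm$branches[[1]]$coef[1] + fm$branches[[2]]$coef[1],
               fsiso$kernels$coef[1], tolerance = 1e-8)
  expect_lt(max(abs(fm$branches[[2]]$coef[-1])), 1e-10)
  expect_equal(fm$fitted$value, fsiso$fitted$value, tolerance = 1e-8)
})

test_that("branch outputs sum to the prediction and respect gate supports", {
  x <- cosine_signal(periods = 18, spp = 15)
  y <- withr::with_seed(60, rnorm(270))
  fit <- fit_miso(x, y, "rect", f0 = 4e6, memory = 1, order = 3)
  pred <- predict(fit)
  br <- attr(pred, "branches")
  expect_equal(br[[1]]$value + br[[2]]$value, pred$value, tolerance = 1e-12)
  # with M = 1 there is no memory spill-over: beyond its constant h0, each
  # branch output is supported on its own gate periods, so the non-constant
  # parts are exactly orthogonal
  v1 <- br[[1]]$value - fit$branches[[1]]$coef[1]
  v2 <- br[[2]]$value - fit$branches[[2]]$coef[1]
  expect_lt(abs(sum(v1 * v2)) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), 1e-10)

  expect_equal(nrow(miso_branches(pred)), 2 * 270)
})

test_that("all-zero output yields an identically zero prediction", {
  x <- cosine_signal(periods = 6, spp = 15)
  fit <- fit_miso(x, rep(0, 90), "hilbert", f0 = 4e6, memory = 2)
  expect_true(all(abs(predict(fit)$value) < 1e-12))
})

test_that("MISO fits model the sub/ultraharmonic lines that SISO misses", {
  b <- default_burst()
  e <- default_echo()
  f0 <- 4e6
  fsiso <- fit_siso(b, e, memory = 19)
  fm1 <- fit_miso(b, e, "rect", f0 = f0, memory = 19)
  fm2 <- fit_miso(b, e, "hilbert", f0 = f0, memory = 19)

  lines_sub <- c(0.5, 1.5, 2.5) * f0
  # analysis window: 240 valid samples = 8 whole subharmonic periods, so the
  # half-integer lines fall on exact FFT bins (no leakage from f0)
  sub_energy <- function(sig) sum(vapply(lines_sub, function(f)
    band_energy(sig$value[31:270], f, fs = 60e6), numeric(1)))
  e_sub <- sub_energy(e)
  expect_lt(sub_energy(fsiso$fitted) / e_sub, 1e-6)   # SISO: no half-lines
  expect_gt(sub_energy(predict(fm1)) / e_sub, 0.5)    # MISO: reproduced
  expect_gt(sub_energy(predict(fm2)) / e_sub, 0.5)

  # and the in-sample error ordering follows
  expect_lt(fm1$rmse_db, fsiso$rmse_db - 5)
  expect_lt(fm2$rmse_db, fsiso$rmse_db - 5)
})

test_that("cross-branch product terms are off by default but available", {
  sys <- make_parallel_system(L = 300, M = 2)
  f0 <- 1 / sys$spp
  plain <- fit_miso(sys$x, sys$y, "rect", f0 = f0, memory = 2, fs = 1)
  expect_null(plain$cross)
  crossed <- fit_miso(sys$x, sys$y, "rect", f0 = f0, memory = 2,
                      cross_terms = TRUE, fs = 1)
  expect_gt(length(crossed$cross$coef), 0)
  expect_lte(crossed$rmse, plain$rmse + 1e-12)
  # prediction path including cross terms is consistent with the fit
  expect_equal(predict(crossed, sys$x)$value, crossed$fitted$value,
               tolerance = 1e-10)
})

test_that("tidy and glance expose branch structure", {
  sys <- make_parallel_system(L = 200, M = 2)
  fit <- fit_miso(sys$x, sys$y, "rect", f0 = 1 / sys$spp, memory = 2, fs = 1)
  td <- tidy(fit)
  expect_equal(unique(td$branch), c("branch_1", "branch_2"))
  expect_equal(nrow(td), 2 * nrow(volterra_terms(2, 3)))
  gl <- glance(fit)
  expect_equal(gl$n_params, 2 * nrow(volterra_terms(2, 3)))
  expect_equal(gl$basis, "rect")
})
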