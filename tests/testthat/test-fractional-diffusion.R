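test_that("spectral symbol has the analytic form and limits", {
  # ln 1 = 0: the log-periodic factor drops out at k = 1 rad/cm
  for (ord in list(fractional_order(1.5, 0.2), fractional_order(2, 0.28),
                   fractional_order(1.1, 0)))
    expect_equal(spectral_symbol(1, ord), -1)
  # classical diffusion limit
  expect_equal(spectral_symbol(2, fractional_order(2, 0)), -4)
  expect_equal(spectral_symbol(c(0, 3), fractional_order(2, 0))[1], 0)
  # generic value
  k <- 7.3; a <- 1.7; b <- 0.25
  expect_equal(spectral_symbol(k, fractional_order(a, b)),
               -k^a * cos(b * log(k)))
})

test_that("apply_H annihilates constants and diagonalizes periodic modes", {
  g <- spectral_grid(64, 0.05)
  ord <- fractional_order(1.6, 0.2)
  expect_equal(apply_H(rep(3.7, 64), g, ord), rep(0, 64), tolerance = 1e-12)
  # sine eigenfunction on a periodic test grid, to near machine precision
  fx <- make_fixture("sine_field", N = 64, dx = 2 * pi / 64, k0 = 1)
  expect_equal(fx$k0, 1)
  H <- apply_H(fx$field, fx$grid, ord, bc = "periodic")
  lam <- spectral_symbol(fx$k0, ord)
  expect_equal(H, lam * fx$field, tolerance = 1e-10)
  # higher mode at generic spacing
  fx2 <- make_fixture("sine_field", N = 128, dx = 0.03215, k0 = 12)
  H2 <- apply_H(fx2$field, fx2$grid, fractional_order(1.8, 0.25),
                bc = "periodic")
  lam2 <- spectral_symbol(fx2$k0, fractional_order(1.8, 0.25))
  expect_lt(max(abs(H2 - lam2 * fx2$field)) / max(abs(lam2 * fx2$field)),
            1e-8)
})

test_that("classical limit matches the finite-difference Laplacian at O(dx^2)", {
  err_at <- function(N) {
    dx <- 2 / N
    x <- (0:(N - 1)) * dx
    f <- exp(-((x - 1) / 0.25)^2)
    g <- spectral_grid(N, dx)
    H <- apply_H(f, g, fractional_order(2, 0))
    fd <- (c(f[-1], f[N - 1]) - 2 * f + c(f[2], f[-N])) / dx^2  # mirror ends
    max(abs(H - fd)[3:(N - 2)])
  }
  e1 <- err_at(64); e2 <- err_at(128)
  # FD error dominates and shrinks ~4x when dx halves
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
})

test_that("propagator conserves the mean, contracts, and forms a semigroup", {
  g <- spectral_grid(48, 0.04)
  ord <- fractional_order(1.7, 0.2)
  set.seed(11)
  f <- rnorm(48)
  op <- diffusion_propagator(g, ord, kappa = 1.2, dt = 0.5)
  f1 <- apply_propagator(op, f)
  expect_equal(mean(f1), mean(f), tolerance = 1e-10)
  # kappa = 0 is the identity
  op0 <- diffusion_propagator(g, ord, kappa = 0, dt = 0.5)
  expect_equal(apply_propagator(op0, f), f, tolerance = 1e-12)
  # semigroup: two half steps equal one full step
  oph <- diffusion_propagator(g, ord, kappa = 1.2, dt = 0.25)
  expect_equal(apply_propagator(oph, apply_propagator(oph, f)), f1,
               tolerance = 1e-10)
  # contraction of every mirrored spectral mode
  spec_mag <- function(v) Mod(stats::fft(c(v, rev(v))))
  expect_true(all(spec_mag(f1) <= spec_mag(f) + 1e-9))
  # cosine-mode decay matches the closed form exp(kappa s(k) t)
  k0 <- g$wavenumbers[6]
  x <- (0:47) * 0.04
  cosf <- cos(k0 * (x + 0.02))  # half-sample offset: an exact mirror mode
  decay <- apply_propagator(op, cosf) / cosf
  expect_equal(decay, rep(exp(1.2 * spectral_symbol(k0, ord) * 0.5e-3), 48),
               tolerance = 1e-8)
})

test_that("stability bound on beta behaves as derived", {
  g_sheet <- spectral_grid(128, 0.03215)
  bmax <- max_stable_beta(g_sheet)
  expect_equal(bmax, 0.3428, tolerance = 1e-3)
  expect_gt(bmax, 0.28)  # the operating range is admissible on this grid
  # beta = 0 is always stable
  expect_true(all(spectral_symbol(g_sheet$wavenumbers,
                                  fractional_order(1.3, 0)) <= 0))
  # coarser grids admit larger beta
  expect_gt(max_stable_beta(spectral_grid(128, 0.0643)),
            max_stable_beta(spectral_grid(128, 0.03215)))
  # constructing a propagator beyond the bound fails, naming beta
  expect_error(
    diffusion_propagator(g_sheet, fractional_order(1.5, 0.4), 1, 0.01),
    "beta = 0.4")
})

test_that("2-D operator acts separably per axis", {
  g <- spectral_grid(32, 0.05, ndim = 2)
  x <- (0:31) * 0.05
  f <- outer(sin(2 * pi * x / 1.6), rep(1, 32))  # varies along x only
  ord <- fractional_order(2, 0)
  H2 <- apply_H(f, g, ord, bc = "periodic")
  g1 <- spectral_grid(32, 0.05)
  H1 <- apply_H(f[, 1], g1, ord, bc = "periodic")
  expect_equal(H2, outer(H1, rep(1, 32)), tolerance = 1e-9)
})
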