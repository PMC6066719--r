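#' Synthetic fixtures for operator and phase-analysis tests
#'
#' Closed-form inputs that exercise the spectral operator and the
#' phase/rotor analysis without running tissue simulations:
#'
#' * `sine_field` — `sin(k0 x)` sampled on a periodic test grid; an exact
#'   eigenfunction of the periodic spectral operator with eigenvalue
#'   `-|k0|^alpha cos(beta ln|k0|)`.
#' * `plane_wave_movie` — a logistic wavefront `V0 + A / (1 + exp((x - c t
#'   - x0)/sigma))` traveling at `c` cm/s; every node crosses any fixed
#'   threshold at times exactly spaced by `dx / c`.
#' * `spiral_movie` — a rigidly rotating spiral `V(r, theta, t) = A cos(theta
#'   - omega t + k r) + V0` centered in the domain: one phase singularity at
#'   the center, rotating at `omega` rad/ms.
#'
#' All fixtures are deterministic; `noise_sd > 0` adds Gaussian noise using
#' the supplied `seed`.
#'
#' @param kind fixture kind.
#' @param N nodes per axis.
#' @param dx spacing, cm.
#' @param k0 wavenumber of the sine field, rad/cm (snapped to the nearest
#'   resolved periodic mode).
#' @param c front speed, cm/s.
#' @param x0 initial front position, cm.
#' @param sigma front width, cm.
#' @param omega angular velocity of the spiral, rad/ms.
#' @param k radial wavenumber of the spiral, rad/cm.
#' @param A,V0 amplitude and offset, mV (defaults span -80 to +20).
#' @param duration movie length, ms.
#' @param frame_dt frame interval, ms.
#' @param chirality +1 or -1 spiral sense.
#' @param noise_sd Gaussian noise s.d., mV.
#' @param seed RNG seed used only when `noise_sd > 0`.
#' @return for `sine_field`: list(`field`, `grid`, `k0`); for movies:
#'   list(`movie` (nodes x frames), `times`, `config`, plus ground-truth
#'   elements (`c` or `omega`, `center`)).
#' @export
make_fixture <- function(kind = c("sine_field", "plane_wave_movie",
                                  "spiral_movie"),
                         N = 64, dx = 0.03215, k0 = 1, c = 63, x0 = 0.2,
                         sigma = 0.05, omega = 2 * pi / 100, k = 2,
                         A = 100, V0 = -80, duration = 500, frame_dt = 1,
                         chirality = 1, noise_sd = 0, seed = 1) {
  kind <- match.arg(kind)
  x <- (0:(N - 1)) * dx
  if (kind == "sine_field") {
    m0 <- max(1, round(k0 * N * dx / (2 * pi)))
    k0s <- 2 * pi * m0 / (N * dx)
    field <- sin(k0s * x)
    return(list(field = field, grid = spectral_grid(N, dx, 1), k0 = k0s))
  }
  times <- seq(0, duration, by = frame_dt)
  if (kind == "plane_wave_movie") {
    cfg <- strand_config(L = N * dx, N = N)
    movie <- vapply(times, function(t)
      V0 + A / (1 + exp((x - c * t / 1000 - x0) / sigma)), numeric(N))
  } else {
    cfg <- sheet_config(N = N, dx = dx)
    cx <- (N - 1) * dx / 2; cy <- cx
    xm <- rep(x, times = N) - cx
    ym <- rep(x, each = N) - cy
    th <- atan2(ym, xm)
    r <- sqrt(xm^2 + ym^2)
    movie <- vapply(times, function(t)
      A * cos(chirality * th - omega * t + k * r) + V0, numeric(N * N))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    movie <- movie + matrix(stats::rnorm(length(movie), 0, noise_sd),
                            nrow(movie))
  }
  out <- list(movie = movie, times = times, config = cfg)
  if (kind == "plane_wave_movie") out$c <- c
  else {
    out$omega <- omega
    out$center <- c((N - 1) * dx / 2, (N - 1) * dx / 2)
  }
  out
}
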