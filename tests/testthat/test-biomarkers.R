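# synthetic action potential: rest -80 mV, instantaneous upstroke to +20 at
# t = 10 ms, then repolarization at exactly 1 mV/ms; APD90 crosses -70 mV
# 90 ms after the upstroke
synthetic_ap <- function(dt = 0.05) {
  t <- seq(0, 200, by = dt)
  v <- ifelse(t < 10, -80, pmax(20 - (t - 10), -80))
  list(t = t, v = v)
}

test_that("activation detection handles flat, square and paced traces", {
  t <- seq(0, 100, by = 0.1)
  expect_identical(activation_times(t, rep(-80, length(t))), numeric(0))
  # square AP crossing -40 between samples at exactly t = 12.0
  v <- ifelse(t >= 11.95, 0, -80)
  v[t >= 60] <- -80
  a <- activation_times(t, v)
  expect_equal(length(a), 1)
  expect_equal(a, 12.0, tolerance = 0.06)
  # refractory lockout merges rapid rebounds
  vr <- rep(-80, length(t)); vr[t %% 10 < 1] <- 0
  expect_true(all(diff(activation_times(t, vr)) >= 50))
})

test_that("APD90 of the synthetic triangular AP is analytically 90 ms", {
  ap <- synthetic_ap()
  a <- activation_times(ap$t, ap$v)
  expect_equal(apd90(ap$t, ap$v, a[1]), 90, tolerance = 0.1)
  # invariance under time shift
  expect_equal(apd90(ap$t + 137, ap$v, a[1] + 137), 90, tolerance = 0.1)
  # invariance under affine voltage maps
  expect_equal(apd90(ap$t, 0.5 * ap$v + 13,
                     activation_times(ap$t, 0.5 * ap$v + 13,
                                      threshold = 0.5 * (-40) + 13)[1]),
               90, tolerance = 0.1)
  # unrepolarized AP is flagged absent
  vtrunc <- ap$v[ap$t <= 60]
  expect_warning(res <- apd90(ap$t[ap$t <= 60], vtrunc, a[1]), "not repolarized")
  expect_true(is.na(res))
})

test_that("conduction velocity is distance over activation delay", {
  # probes 0.667 cm apart activating 10 ms apart: CV = 66.7 cm/s
  t <- seq(0, 100, by = 0.01)
  v1 <- ifelse(t >= 20, 0, -80)
  v2 <- ifelse(t >= 30, 0, -80)
  fake <- structure(list(
    probe_v = cbind(v1, v2), probe_times = t, probes = c(10L, 20L),
    config = strand_config(N = 30, L = 30 * 0.0667)), class = "sim_result")
  expect_equal(conduction_velocity(fake), 66.7, tolerance = 0.1)
  # affine voltage rescaling does not move the measured CV appreciably
  fake$probe_v <- 0.7 * fake$probe_v + 5
  expect_equal(conduction_velocity(fake), 66.7, tolerance = 0.5)
  # constructed plane wave at 63 cm/s is recovered
  fx <- make_fixture("plane_wave_movie", N = 64, dx = 0.03215, c = 63,
                     frame_dt = 0.05, duration = 60)
  p1 <- 22L; p2 <- 43L
  fake2 <- structure(list(probe_v = t(fx$movie[c(p1, p2), ]),
                          probe_times = fx$times, probes = c(p1, p2),
                          config = fx$config), class = "sim_result")
  expect_equal(conduction_velocity(fake2), 63, tolerance = 0.5)
})

test_that("APD dispersion identities hold on constructed profiles", {
  # build a strand movie with square APs of known durations
  t <- seq(0, 300, by = 0.5)
  mk <- function(apd) ifelse(t >= 50 & t <= 50 + apd, 20, -80)
  apds <- c(rep(100, 6), rep(95, 5), rep(90, 5))
  cfg <- strand_config(N = 16, L = 1.6)
  res <- structure(list(movie = t(vapply(apds, mk, numeric(length(t)))),
                        movie_times = t, config = cfg),
                   class = "sim_result")
  prof <- apd_dispersion(res, edge_exclude = 0)
  expect_equal(attr(prof, "global_dapd"), 10, tolerance = 0.5)
  expect_equal(prof$local_dapd, 90 - apds, tolerance = 0.5)
  expect_true(all(prof$local_dapd <= 0))
  # uniform field: zero dispersion everywhere
  res$movie <- t(vapply(rep(95, 16), mk, numeric(length(t))))
  prof0 <- apd_dispersion(res, edge_exclude = 0)
  expect_equal(attr(prof0, "global_dapd"), 0, tolerance = 1e-6)
  expect_equal(prof0$local_dapd, rep(0, 16), tolerance = 1e-6)
})

test_that("peak current profiles have one row per node and vanish at rest", {
  cfg <- strand_config(N = 24, L = 1, kappa = 0.4)
  res <- run_simulation(cfg, membrane_state(), list(), 10, base_params(),
                        record = list(movie_dt = 0, peaks = TRUE))
  prof <- peak_current_profiles(res)
  expect_equal(nrow(prof), 4 * 24)
  expect_true(all(prof$peak[prof$current == "I_Na"] < 0.02))
  expect_setequal(unique(prof$current), c("I_Na", "I_to", "I_Kur", "I_CaL"))
})
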