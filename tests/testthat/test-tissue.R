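test_that("uniform initialization carries N identical copies with zero gradient", {
  cfg <- strand_config(N = 32, L = 1)
  ts <- initialize_tissue(cfg, caf_init_400())
  expect_equal(dim(ts$states), c(21, 32))
  expect_true(all(ts$states == as.numeric(caf_init_400())))
  H <- apply_H(ts$states[1, ], config_grid(cfg), cfg$order)
  expect_equal(H, rep(0, 32), tolerance = 1e-10)
})

test_that("kappa = 0 tissue equals independent single cells exactly", {
  cfg <- strand_config(N = 16, L = 0.25, kappa = 0)
  stim <- stimulus_spec(seq_len(16), 5, 25)  # stimulate every node alike
  res <- run_simulation(cfg, membrane_state(), list(stim), 60, base_params(),
                        record = list(movie_dt = 0, probes = c(1, 8)))
  single <- pace_cell(base_params(), bcl = 100, duration = 60,
                      stim_amplitude = 25, first_onset = 5, record_dt = 0.01)
  # all nodes identical, and identical to the isolated cell trajectory
  expect_identical(res$probe_v[, 1], res$probe_v[, 2])
  expect_equal(res$probe_v[, 1], single$trace$V, tolerance = 1e-12)
})

test_that("quiescent uniform tissue is a fixed point and runs are deterministic", {
  cfg <- strand_config(N = 32, L = 1, kappa = 0.4)
  r1 <- run_simulation(cfg, membrane_state(), list(), 20, base_params(),
                       record = list(movie_dt = 1, probes = 16))
  expect_lt(max(abs(r1$probe_v - membrane_state()[["V"]])), 0.05)
  r2 <- run_simulation(cfg, membrane_state(), list(), 20, base_params(),
                       record = list(movie_dt = 1, probes = 16))
  expect_identical(r1$movie, r2$movie)      # bit-identical reruns
  expect_identical(r1$probe_v, r2$probe_v)
  # doubling the record stride halves the frame count
  r3 <- run_simulation(cfg, membrane_state(), list(), 20, base_params(),
                       record = list(movie_dt = 2))
  expect_equal(ncol(r3$movie), (ncol(r1$movie) - 1) / 2 + 1)
})

test_that("split scheme matches the analytic heat-kernel decay without reaction", {
  # all-conductances-zero cell: reaction contributes nothing to V
  dead <- ionic_params()
  dead$values[1:14] <- 0
  N <- 64; L <- 2
  cfg <- strand_config(N = N, L = L, kappa = 1.5, k_power_ref = 1)
  x <- (0:(N - 1)) * cfg$dx
  k0 <- config_grid(cfg)$wavenumbers[5]
  f0 <- -80 + 5 * cos(k0 * (x + cfg$dx / 2))
  init <- initialize_tissue(cfg, membrane_state())
  init$states[1, ] <- f0
  res <- run_simulation(cfg, init, list(), 50, dead,
                        record = list(movie_dt = 50))
  vT <- res$movie[, ncol(res$movie)]
  decay_num <- (vT + 80) / (f0 + 80)
  decay_ana <- exp(1.5 * spectral_symbol(k0, cfg$order) * 50e-3)
  expect_equal(mean(decay_num), decay_ana, tolerance = 0.01)
})

test_that("strang splitting is available and close to lie at dt = 0.01", {
  cfg <- strand_config(N = 32, L = 1, kappa = 0.4)
  stim <- stimulus_spec(1:3, 5, 40)
  r_lie <- run_simulation(cfg, membrane_state(), list(stim), 40,
                          base_params(), record = list(movie_dt = 0, probes = 20))
  r_str <- run_simulation(cfg, membrane_state(), list(stim), 40,
                          base_params(), record = list(movie_dt = 0, probes = 20),
                          splitting = "strang")
  a_lie <- activation_times(r_lie$probe_times, r_lie$probe_v[, 1])
  a_str <- activation_times(r_str$probe_times, r_str$probe_v[, 1])
  expect_equal(length(a_lie), 1)
  expect_equal(a_lie, a_str, tolerance = 0.02)
})

test_that("conduction velocity increases with kappa at fixed alpha", {
  cv1 <- cardiofrac:::strand_cv(strand_config(N = 64, kappa = 0.25),
                                base_params(), membrane_state(), 40,
                                n_beats = 1)
  cv2 <- cardiofrac:::strand_cv(strand_config(N = 64, kappa = 0.8),
                                base_params(), membrane_state(), 40,
                                n_beats = 1)
  expect_gt(cv2, cv1)
})

test_that("instability and mismatches raise informative errors", {
  cfg <- strand_config(N = 32, L = 1)
  expect_error(run_simulation(cfg, membrane_state()[1:5], list(), 10,
                              base_params()), "21")
  # overdriving the voltage beyond 200 mV aborts with a time stamp
  stim <- stimulus_spec(1:32, 1, 5000, duration = 50)
  expect_error(run_simulation(cfg, membrane_state(), list(stim), 50,
                              base_params(), record = list(movie_dt = 0)),
               "200 mV")
})
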