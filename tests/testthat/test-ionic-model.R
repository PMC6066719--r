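test_that("membrane currents balance at the published resting state", {
  cur <- ionic_currents(membrane_state(), base_params())
  # quiescence: total current nearly zero at the published steady state
  expect_lt(abs(cur$I_total), 0.05)
  # decomposition: I_total is exactly the sum of the components
  comps <- unlist(cur[c("I_Na", "I_K1", "I_to", "I_Kur", "I_Kr", "I_Ks",
                        "I_CaL", "I_NaK", "I_NaCa", "I_bNa", "I_bCa",
                        "I_pCa", "I_KACh")])
  expect_equal(cur$I_total, sum(comps), tolerance = 1e-12)
  # no agonist, no remodeling: the cholinergic current vanishes
  expect_identical(cur$I_KACh, 0)
})

test_that("sodium current is inward during the upstroke", {
  s <- membrane_state(V = -35, m = 0.5, h = 0.8, j = 0.9)
  cur <- ionic_currents(s, base_params())
  expect_lt(cur$I_Na, 0)
})

test_that("CAF remodeling rescales exactly the reported conductances", {
  p0 <- ionic_params()
  p1 <- apply_caf_remodeling(p0)
  expect_equal(p1$values[["g_to"]], 0.65 * p0$values[["g_to"]])
  expect_equal(p1$values[["g_CaL"]], 0.65 * p0$values[["g_CaL"]])
  expect_equal(p1$values[["g_Kur_scale"]], 0.49 * p0$values[["g_Kur_scale"]])
  expect_equal(p1$values[["g_K1"]], 2.1 * p0$values[["g_K1"]])
  # currents not listed in the remodeling are untouched
  expect_identical(p1$values[["g_Kr"]], p0$values[["g_Kr"]])
  expect_identical(p1$values[["g_Na"]], p0$values[["g_Na"]])
  expect_equal(p1$values[["ACh_nM"]], 5)
  expect_true(p1$remodeled)
  expect_error(apply_caf_remodeling(p1), "already")
})

test_that("acetylcholine-activated current has the expected structure", {
  EK <- -86.9
  # zero driving force and zero agonist both give zero current
  expect_equal(i_kach(EK, EK, 5), 0)
  expect_equal(i_kach(-80, EK, 0), 0)
  expect_error(i_kach(-80, EK, -1), ">= 0")
  # inward rectification: conductance larger at hyperpolarized potentials
  g_neg <- i_kach(-100, EK, 5) / (-100 - EK)
  g_pos <- i_kach(0, EK, 5) / (0 - EK)
  expect_gt(g_neg, g_pos)
  # dose-response saturates toward a finite maximal conductance
  vf <- 0.0517 + 0.4516 / (1 + exp((-80 + 59.53) / 17.18))
  g1 <- i_kach(-80, EK, 5) / (-80 - EK)
  g3 <- i_kach(-80, EK, 5e7) / (-80 - EK)
  expect_gt(g3 / g1, 10)               # 5 nM is far below saturation
  expect_gt(g3, 0.9 * 10 * vf)         # within 10% of the asymptote
  # frozen value of the transcribed formulation at V = -80, 5 nM ACh:
  # dose factor 10 / (1 + 9.13652 / 0.005^0.477811)
  dose <- 10 / (1 + 9.13652 / 0.005^0.477811)
  expect_equal(i_kach(-80, EK, 5), dose * vf * (-80 - EK), tolerance = 1e-10)
})

test_that("explicit Euler stepping is a first-order fixed-point scheme", {
  s0 <- membrane_state()
  # resting state is (nearly) a fixed point of one step
  s1 <- step_cell(s0, base_params(), I_stim = 0, dt = 0.01)
  expect_lt(abs(s1[["V"]] - s0[["V"]]), 1e-4)
  # Richardson: halving dt roughly halves the error after 1 ms from a
  # perturbed state (first-order convergence)
  sp <- membrane_state(V = -60)
  advance <- function(dt) {
    s <- as.numeric(sp)
    for (i in seq_len(round(1 / dt)))
      s <- cardiofrac:::cpp_step_cell_exact(s, cardiofrac:::par_vec(base_params()), 0, dt)
    s[1]
  }
  v_ref <- advance(0.00125)
  e1 <- abs(advance(0.01) - v_ref)
  e2 <- abs(advance(0.005) - v_ref)
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
})

test_that("a suprathreshold pulse elicits an action potential", {
  tr <- pace_cell(base_params(), bcl = 500, duration = 500,
                  stim_amplitude = 2 * cell_thr())
  expect_gt(max(tr$trace$V), 0)
  g <- glance(tr)
  expect_gt(g$apd90, 100)
})

test_that("the unstimulated cell stays at rest for 10 s", {
  res <- cardiofrac:::cpp_run_tissue(matrix(as.numeric(membrane_state()), 21, 1),
                        matrix(0, 0, 0), matrix(0, 0, 0), 1L, 1L, 0.01,
                        1000000L, 0, numeric(0), numeric(0), numeric(0),
                        integer(0), list(integer(0)),
                        cardiofrac:::par_vec(base_params()),
                        0L, 0L, 0L, FALSE, 0L, FALSE, FALSE)
  drift <- abs(res$probe_v[, 1] - membrane_state()[["V"]])
  expect_lt(max(drift), 0.5)
  # gates stay within [0, 1] throughout
  expect_gte(res$gate_min, 0)
  expect_lte(res$gate_max, 1)
})

test_that("CAF remodeling shortens the APD and hyperpolarizes rest", {
  gb <- glance(paced_60s(base_params(), "pace_base"))
  gc <- glance(paced_60s(caf_params(), "pace_caf"))
  expect_lt(gc$apd90, gb$apd90)
  expect_lt(gc$v_rest, gb$v_rest)
})

test_that("invalid states and parameters are rejected", {
  expect_error(ionic_params(g_Na = -1), ">= 0")
  expect_error(ionic_params(bogus = 1), "unknown")
  s <- membrane_state()
  s[1] <- NaN
  expect_error(ionic_currents(s, base_params()), "non-finite")
  expect_error(step_cell(membrane_state(V = 250), base_params()), "200 mV")
})
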