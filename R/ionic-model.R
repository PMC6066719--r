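#' @useDynLib cardiofrac, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import tibble
#' @importFrom rlang abort warn `%||%`
NULL

STATE_NAMES <- c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                 "d", "f", "fCa", "u", "v", "w", "Nai", "Ki", "Cai",
                 "Ca_up", "Ca_rel")

PARAM_NAMES <- c("g_Na", "g_K1", "g_to", "g_Kr", "g_Ks", "g_CaL",
                 "g_Kur_scale", "g_bNa", "g_bCa", "I_NaK_max", "I_NaCa_max",
                 "I_pCa_max", "I_up_max", "k_rel", "ACh_nM", "C")

#' Courtemanche-Ramirez-Nattel ionic parameter set
#'
#' Baseline maximal conductances (nS/pF), pump/exchanger maxima (pA/pF) and
#' membrane capacitance (pF) of the human atrial membrane model. `I_Kur` has a
#' voltage-dependent conductance; `g_Kur_scale` multiplies it. The
#' acetylcholine-activated potassium current is controlled by the agonist
#' concentration `ACh_nM` (nM); at 0 it vanishes.
#'
#' @param ACh_nM acetylcholine concentration in nM (>= 0).
#' @param ... named overrides of individual parameters (see `PARAM_NAMES`).
#' @return an object of class `ionic_params`.
#' @export
#' @examples
#' p <- ionic_params()
#' p_caf <- apply_caf_remodeling(p)
ionic_params <- function(ACh_nM = 0, ...) {
  p <- c(g_Na = 7.8, g_K1 = 0.09, g_to = 0.1652, g_Kr = 0.029411765,
         g_Ks = 0.12941176, g_CaL = 0.12375, g_Kur_scale = 1.0,
         g_bNa = 0.0006744375, g_bCa = 0.001131, I_NaK_max = 0.59933874,
         I_NaCa_max = 1600, I_pCa_max = 0.275, I_up_max = 0.005,
         k_rel = 30, ACh_nM = ACh_nM, C = 100)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), PARAM_NAMES)
    if (length(bad)) abort(paste("unknown ionic parameters:", paste(bad, collapse = ", ")))
    p[names(dots)] <- unlist(dots)
  }
  if (any(p[1:14] < 0)) abort("conductances and maxima must be >= 0")
  if (p[["ACh_nM"]] < 0) abort("ACh_nM must be >= 0")
  if (p[["C"]] <= 0) abort("membrane capacitance must be > 0")
  structure(list(values = p, remodeled = FALSE), class = "ionic_params")
}

#' @export
print.ionic_params <- function(x, ...) {
  cat("<ionic_params>", if (x$remodeled) "(CAF remodeled)" else "(baseline)", "\n")
  print(x$values)
  invisible(x)
}

# flat numeric vector in the layout the compiled kernel expects
par_vec <- function(params) {
  stopifnot(inherits(params, "ionic_params"))
  unname(params$values[PARAM_NAMES])
}

#' Apply chronic-AF electrical remodeling
#'
#' Rescales maximal conductances according to the chronic atrial fibrillation
#' remodeling used throughout the package: `g_to` and `g_CaL` are multiplied
#' by 0.65, the `I_Kur` conductance scale by 0.49 and `g_K1` by 2.1. The
#' acetylcholine-activated potassium current is enabled at `ACh_nM`
#' (default 5 nM). Double application is rejected.
#'
#' @param params an `ionic_params` object with `remodeled = FALSE`.
#' @param ACh_nM acetylcholine concentration of the remodeled set, nM.
#' @return the remodeled `ionic_params`.
#' @export
apply_caf_remodeling <- function(params, ACh_nM = 5) {
  stopifnot(inherits(params, "ionic_params"))
  if (params$remodeled) abort("parameters are already CAF-remodeled")
  v <- params$values
  v["g_to"] <- v["g_to"] * 0.65
  v["g_CaL"] <- v["g_CaL"] * 0.65
  v["g_Kur_scale"] <- v["g_Kur_scale"] * 0.49
  v["g_K1"] <- v["g_K1"] * 2.1
  v["ACh_nM"] <- ACh_nM
  structure(list(values = v, remodeled = TRUE), class = "ionic_params")
}

#' Default membrane state
#'
#' The published resting steady state of the Courtemanche model: membrane
#' potential (mV), 15 gating variables, intracellular Na+/K+/Ca2+ and the two
#' sarcoplasmic-reticulum calcium compartments (mM).
#'
#' @param ... named overrides of individual state variables.
#' @return a named numeric vector of class `membrane_state` (length 21).
#' @export
membrane_state <- function(...) {
  s <- c(V = -81.18, m = 2.908e-3, h = 0.9649, j = 0.9775, oa = 3.043e-2,
         oi = 0.9992, ua = 4.966e-3, ui = 0.9986, xr = 3.296e-5,
         xs = 1.869e-2, d = 1.367e-4, f = 0.9996, fCa = 0.7755, u = 0,
         v = 1, w = 0.9992, Nai = 11.17, Ki = 139.0, Cai = 1.013e-4,
         Ca_up = 1.488, Ca_rel = 1.488)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), STATE_NAMES)
    if (length(bad)) abort(paste("unknown state variables:", paste(bad, collapse = ", ")))
    s[names(dots)] <- unlist(dots)
  }
  structure(s, class = "membrane_state")
}

validate_membrane_state <- function(state) {
  if (length(state) != 21) abort("membrane state must have 21 variables")
  if (any(!is.finite(state))) abort("non-finite value in membrane state")
  g <- state[2:16]
  if (any(g < 0 | g > 1)) warn("gate variable outside [0, 1]")
  if (any(state[17:21] <= 0)) abort("concentrations must be positive")
  invisible(state)
}

#' Acetylcholine-activated potassium current
#'
#' Inwardly rectifying K+ current with a saturating acetylcholine
#' dose-response (half-saturation in the sub-micromolar range), proportional
#' to the driving force `V - E_K`. Vanishes at `ACh_nM = 0` and at `V = E_K`.
#'
#' @param V membrane potential, mV (vectorized).
#' @param E_K potassium Nernst potential, mV.
#' @param ACh_nM acetylcholine concentration, nM (>= 0).
#' @return current density in pA/pF.
#' @export
i_kach <- function(V, E_K, ACh_nM) {
  if (any(ACh_nM < 0)) abort("ACh_nM must be >= 0")
  mapply(cpp_ikach, V, E_K, ACh_nM)
}

#' All membrane currents at a state
#'
#' Evaluates every component current of the atrial membrane model (exact
#' formulas, no lookup tables) and their sum.
#'
#' @param state a `membrane_state`.
#' @param params an `ionic_params`.
#' @param time timestamp attached to the record, ms.
#' @return a one-row tibble with the 13 component currents, `I_total`
#'   (pA/pF) and `time` (ms).
#' @export
ionic_currents <- function(state, params, time = 0) {
  validate_membrane_state(state)
  cur <- cpp_ionic_currents(as.numeric(state), par_vec(params))
  out <- as_tibble(as.list(cur))
  out$time <- time
  out
}

#' Advance a single cell one explicit-Euler step
#'
#' All 21 state variables are advanced by one forward-Euler step of length
#' `dt`. Gates are not artificially clipped; values leaving `[0, 1]` raise a
#' warning. `|V| > 200` mV aborts with a diagnostic.
#'
#' @param state a `membrane_state`.
#' @param params an `ionic_params`.
#' @param I_stim stimulus current density, pA/pF (positive = depolarizing).
#' @param dt time step, ms (reference 0.01).
#' @return the advanced `membrane_state`.
#' @export
step_cell <- function(state, params, I_stim = 0, dt = 0.01) {
  if (dt <= 0) abort("dt must be > 0")
  if (any(!is.finite(state))) abort("non-finite value in membrane state")
  if (abs(state[[1]]) > 200) abort("instability: |V| > 200 mV")
  out <- cpp_step_cell_exact(as.numeric(state), par_vec(params), -I_stim, dt)
  names(out) <- STATE_NAMES
  g <- out[2:16]
  if (any(g < -1e-12 | g > 1 + 1e-12))
    warn("gate variable left [0, 1] after Euler step")
  structure(out, class = "membrane_state")
}

#' Diastolic threshold of an isolated cell
#'
#' Bisection (to 1% relative precision) on the amplitude of a rectangular
#' pulse for the minimal amplitude that elicits an action potential
#' (peak V > 0 mV) in a resting cell.
#'
#' @param params an `ionic_params`.
#' @param init initial `membrane_state`.
#' @param stim_duration pulse duration, ms.
#' @param bracket initial amplitude bracket, pA/pF.
#' @return threshold amplitude in pA/pF.
#' @export
find_cell_threshold <- function(params, init = membrane_state(),
                                stim_duration = 2, bracket = c(0.5, 60)) {
  pv <- par_vec(params)
  fires <- function(amp) {
    res <- cpp_run_tissue(matrix(as.numeric(init), 21, 1),
                         matrix(0, 0, 0), matrix(0, 0, 0), 1L, 1L, 0.01,
                         2000L, 0, 1, stim_duration, amp, 0L, list(0L), pv,
                         0L, 0L, 0L, FALSE, 0L, FALSE, FALSE)
    max(res$probe_v[, 1]) > 0
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (fires(lo)) return(lo)
  if (!fires(hi)) abort("no capture at top of threshold bracket")
  while ((hi - lo) / hi > 0.01) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Pace an isolated cell
#'
#' Applies a train of rectangular current pulses to a single cell and records
#' the voltage trace. The final state is the standard initial condition for
#' tissue simulations.
#'
#' @param params an `ionic_params`.
#' @param bcl basic cycle length, ms.
#' @param duration total paced time, ms.
#' @param stim_amplitude pulse amplitude in pA/pF; `NULL` uses twice the
#'   diastolic threshold of the cell.
#' @param stim_duration pulse duration, ms (reference 2).
#' @param init initial `membrane_state`.
#' @param dt Euler step, ms.
#' @param record_dt sampling interval of the returned trace, ms.
#' @param first_onset time of the first pulse, ms.
#' @return an object of class `pace_trace`: list with `trace` (tibble of
#'   `time`, `V`), `final_state`, `onsets`, `params`, `captured` (fraction of
#'   stimuli that elicited an upstroke).
#' @export
pace_cell <- function(params, bcl, duration, stim_amplitude = NULL,
                      stim_duration = 2, init = membrane_state(), dt = 0.01,
                      record_dt = 0.05, first_onset = 10) {
  if (bcl <= stim_duration) abort("bcl must exceed stim_duration")
  if (is.null(stim_amplitude))
    stim_amplitude <- 2 * find_cell_threshold(params, init, stim_duration)
  onsets <- seq(first_onset, duration - stim_duration, by = bcl)
  n <- length(onsets)
  stride <- max(1L, as.integer(round(record_dt / dt)))
  res <- cpp_run_tissue(matrix(as.numeric(init), 21, 1),
                       matrix(0, 0, 0), matrix(0, 0, 0), 1L, 1L, dt,
                       as.integer(round(duration / dt)), 0,
                       onsets, rep(stim_duration, n), rep(stim_amplitude, n),
                       rep(0L, n), list(0L), par_vec(params),
                       stride, 0L, integer(0), FALSE, 0L, FALSE, FALSE)
  if (nzchar(res$error))
    abort(paste0(res$error, " at t = ", res$abort_step * dt, " ms"))
  v <- as.numeric(res$movie[1, ])
  t <- as.numeric(res$movie_times)
  acts <- activation_times(t, v)
  captured <- length(acts) / n
  if (captured < 1 - 1e-9)
    warn(sprintf("loss of 1:1 capture: %d activations for %d stimuli",
                 length(acts), n))
  fs <- as.numeric(res$state[, 1]); names(fs) <- STATE_NAMES
  structure(list(trace = tibble(time = t, V = v),
                 final_state = structure(fs, class = "membrane_state"),
                 onsets = onsets, bcl = bcl, params = params,
                 stim_amplitude = stim_amplitude, captured = captured,
                 gate_range = c(res$gate_min, res$gate_max)),
            class = "pace_trace")
}

#' @export
print.pace_trace <- function(x, ...) {
  cat("<pace_trace>", length(x$onsets), "stimuli at BCL", x$bcl, "ms\n")
  g <- glance(x)
  cat(sprintf("  last-beat APD90 %.1f ms, diastolic V %.2f mV\n",
              g$apd90, g$v_rest))
  invisible(x)
}
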