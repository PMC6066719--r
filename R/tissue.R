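#' Strand (1-D) tissue configuration
#'
#' A cable of atrial cells of length `L` cm discretized at `N` nodes, coupled
#' by the complex fractional-order diffusion operator.
#'
#' The diffusion coefficient `kappa` is entered in the calibrated convention
#' of the conduction-velocity tables (cm^2/s): the spectral substep uses the
#' effective coefficient `kappa * k_power_ref^(-alpha)`, where
#' `k_power_ref` (rad/cm) is the reference wavenumber of the power-law
#' normalization. The default `k_power_ref = 0.5` is pinned by requiring
#' that `kappa = 0.40` cm^2/s at `gamma = 2 + j0` propagates non-remodeled
#' plane waves at 63 cm/s; set it to 1 for the raw spectral convention.
#'
#' @param L strand length, cm.
#' @param N nodes (>= 16).
#' @param dt Euler step, ms (in (0, 0.05]).
#' @param kappa diffusion coefficient, cm^2/s (table convention).
#' @param order a [fractional_order()].
#' @param k_power_ref power-law reference wavenumber, rad/cm.
#' @return a `tissue_config`.
#' @export
strand_config <- function(L = 2, N = 128, dt = 0.01, kappa = 0.40,
                          order = fractional_order(2, 0), k_power_ref = 0.5) {
  if (L <= 0) abort("L must be > 0")
  if (N < 16) abort("N must be >= 16")
  if (dt <= 0 || dt > 0.05) abort("dt must be in (0, 0.05]")
  structure(list(ndim = 1L, L = L, N = as.integer(N), dx = L / N, dt = dt,
                 kappa = kappa, order = order, k_power_ref = k_power_ref),
            class = "tissue_config")
}

#' Sheet (2-D) tissue configuration
#'
#' A square sheet of `N x N` nodes at spacing `dx` cm per axis. The reference
#' geometry is the 321.5-um grid with `N = 128` (a 4.115-cm domain; the
#' nominal 4-cm domain is rounded up to a power-of-two transform size).
#' See [strand_config()] for the `kappa` convention.
#'
#' @param N nodes per axis.
#' @param dx = dy spacing, cm.
#' @param dt Euler step, ms.
#' @param kappa diffusion coefficient, cm^2/s (table convention).
#' @param order a [fractional_order()].
#' @param k_power_ref power-law reference wavenumber, rad/cm.
#' @return a `tissue_config`.
#' @export
sheet_config <- function(N = 128, dx = 0.03215, dt = 0.01, kappa = 0.40,
                         order = fractional_order(2, 0), k_power_ref = 0.5) {
  if (N < 16) abort("N must be >= 16")
  if (dx <= 0) abort("dx must be > 0")
  if (dt <= 0 || dt > 0.05) abort("dt must be in (0, 0.05]")
  structure(list(ndim = 2L, L = N * dx, N = as.integer(N), dx = dx, dt = dt,
                 kappa = kappa, order = order, k_power_ref = k_power_ref),
            class = "tissue_config")
}

#' @export
print.tissue_config <- function(x, ...) {
  cat(sprintf("<tissue_config> %dD, N = %d, dx = %g cm, dt = %g ms, kappa = %g cm^2/s, gamma = %g + j%g\n",
              x$ndim, x$N, x$dx, x$dt, x$kappa, x$order$alpha, x$order$beta))
  invisible(x)
}

n_cells <- function(config) if (config$ndim == 1) config$N else config$N^2

#' Spectral grid of a tissue configuration
#'
#' @param config a `tissue_config`.
#' @return the [spectral_grid()] the configuration's operator acts on.
#' @export
config_grid <- function(config) spectral_grid(config$N, config$dx, config$ndim)

effective_kappa <- function(config) {
  config$kappa * config$k_power_ref^(-config$order$alpha)
}

config_operator <- function(config) {
  diffusion_propagator(config_grid(config), config$order,
                       effective_kappa(config), config$dt)
}

#' Rectangular stimulus specification
#'
#' @param region integer vector of 1-based node indices receiving the pulse
#'   (for 2-D sheets, indices into the column-major `N x N` field).
#' @param onsets pulse onset times, ms.
#' @param amplitude pulse amplitude, pA/pF (positive = depolarizing);
#'   conventionally twice the diastolic threshold.
#' @param duration pulse duration, ms (reference 2).
#' @return a `stimulus_spec`.
#' @export
stimulus_spec <- function(region, onsets, amplitude, duration = 2) {
  if (duration <= 0) abort("duration must be > 0")
  if (!length(region)) abort("stimulus region is empty")
  structure(list(region = as.integer(region), onsets = as.numeric(onsets),
                 amplitude = amplitude, duration = duration),
            class = "stimulus_spec")
}

#' Stimulation region helpers
#'
#' `region_left_edge()` selects the first `width` nodes of a strand, or the
#' full left column(s) of a sheet; `region_lower_left_quadrant()` the quarter
#' of a sheet adjacent to that edge; `region_mid_cell()` the middle node.
#'
#' @param config a `tissue_config`.
#' @param width number of node columns, in nodes.
#' @return integer node indices (1-based).
#' @export
region_left_edge <- function(config, width = 5) {
  if (config$ndim == 1) return(seq_len(min(width, config$N)))
  N <- config$N
  as.integer(outer(seq_len(min(width, N)), (0:(N - 1)) * N, `+`))
}

#' @rdname region_left_edge
#' @export
region_lower_left_quadrant <- function(config) {
  stopifnot(config$ndim == 2)
  N <- config$N
  half <- seq_len(N %/% 2)
  as.integer(outer(half, (half - 1) * N, `+`))
}

#' @rdname region_left_edge
#' @export
region_mid_cell <- function(config) {
  if (config$ndim == 1) return(as.integer(round(config$N / 2)))
  N <- config$N
  as.integer(round(N / 2) + (round(N / 2) - 1) * N)
}

#' Initialize a tissue from a single-cell state
#'
#' Every node receives an identical copy of `state` — by convention the final
#' state of a cell paced for 60 s at a basic cycle length of 400 ms (see
#' [pace_cell()]).
#'
#' @param config a `tissue_config`.
#' @param state a `membrane_state`.
#' @return a `tissue_state` (21 x n_cells matrix with config attached).
#' @export
initialize_tissue <- function(config, state) {
  if (length(state) != 21) abort("state must be a 21-variable membrane state")
  m <- matrix(as.numeric(state), 21, n_cells(config))
  structure(list(states = m, config = config), class = "tissue_state")
}

record_defaults <- function(config, movie_dt = 1, probes = integer(0),
                            movie_start = 0, peaks = FALSE, peaks_start = 0,
                            probe_currents = FALSE) {
  list(movie_dt = movie_dt, probes = as.integer(probes),
       movie_start = movie_start, peaks = peaks, peaks_start = peaks_start,
       probe_currents = probe_currents)
}

#' Run a tissue simulation
#'
#' Integrates the monodomain system by operator splitting: each step performs
#' an explicit-Euler reaction update of every node (including any active
#' stimulus current) followed by the exact spectral diffusion propagator
#' applied to the voltage field only (Lie splitting; `splitting = "strang"`
#' surrounds the reaction with two half diffusion steps). Deterministic:
#' identical inputs give bit-identical results.
#'
#' @param config a `tissue_config`.
#' @param init a `tissue_state` (or `membrane_state`, replicated to all
#'   nodes).
#' @param stimuli list of [stimulus_spec()] objects.
#' @param duration simulated time, ms.
#' @param record list from `record_defaults()`-style arguments: `movie_dt`
#'   (frame interval in ms, 0 disables), `probes` (1-based node indices
#'   recorded every step), `movie_start` (ms), `peaks` (track per-node peak
#'   magnitudes of I_Na, I_to, I_Kur, I_CaL), `peaks_start` (ms),
#'   `probe_currents` (record the four currents at the probes each step).
#' @param params an `ionic_params`.
#' @param t0 initial time, ms (stimulus onsets are absolute).
#' @param splitting `"lie"` or `"strang"`.
#' @return a `sim_result`: `movie` (n_cells x frames), `movie_times`,
#'   `probe_v` (steps+1 x probes), `probe_times`, `peaks`, `final`,
#'   `config`, `stimuli`, `gate_range`.
#' @export
run_simulation <- function(config, init, stimuli, duration, params,
                           record = list(), t0 = 0,
                           splitting = c("lie", "strang")) {
  splitting <- match.arg(splitting)
  rec <- do.call(record_defaults, c(list(config = config), record))
  if (!inherits(init, "tissue_state")) {
    if (!is.numeric(init) || length(init) != 21)
      abort("init must be a tissue_state or a 21-variable membrane state")
    init <- initialize_tissue(config, init)
  }
  if (ncol(init$states) != n_cells(config)) abort("state/config mismatch")
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)

  # kappa = 0 decouples the cells exactly: skip the diffusion substep
  op <- if (config$kappa > 0) config_operator(config) else NULL
  onsets <- numeric(0); durs <- numeric(0); amps <- numeric(0); mask_id <- integer(0)
  masks <- list()
  for (i in seq_along(stimuli)) {
    st <- stimuli[[i]]
    masks[[i]] <- st$region - 1L
    onsets <- c(onsets, st$onsets)
    durs <- c(durs, rep(st$duration, length(st$onsets)))
    amps <- c(amps, rep(st$amplitude, length(st$onsets)))
    mask_id <- c(mask_id, rep(i - 1L, length(st$onsets)))
  }
  if (!length(masks)) masks <- list(integer(0))

  dt <- config$dt
  nsteps <- as.integer(round(duration / dt))
  stride <- if (rec$movie_dt > 0) max(1L, as.integer(round(rec$movie_dt / dt))) else 0L
  Px <- if (is.null(op)) matrix(0, 0, 0) else op$P
  Py <- if (!is.null(op) && config$ndim == 2) op$P else matrix(0, 0, 0)
  nx <- config$N
  ny <- if (config$ndim == 2) config$N else 1L

  res <- cpp_run_tissue(init$states, Px, Py, nx, ny, dt, nsteps, t0,
                        onsets, durs, amps, mask_id, masks, par_vec(params),
                        stride, as.integer(round(rec$movie_start / dt)),
                        rec$probes - 1L, rec$peaks,
                        as.integer(round(rec$peaks_start / dt)),
                        splitting == "strang", rec$probe_currents)
  if (nzchar(res$error))
    abort(sprintf("%s at t = %.2f ms", res$error, t0 + res$abort_step * dt))
  if (res$gate_min < -1e-10 || res$gate_max > 1 + 1e-10)
    warn(sprintf("gate variables left [0,1]: range [%.3g, %.3g]",
                 res$gate_min, res$gate_max))

  final <- structure(list(states = res$state, config = config),
                     class = "tissue_state")
  pt <- t0 + (0:nsteps) * dt
  structure(list(movie = if (stride > 0) res$movie else NULL,
                 movie_times = if (stride > 0) as.numeric(res$movie_times) else NULL,
                 probe_v = if (length(rec$probes)) res$probe_v else NULL,
                 probe_currents = if (rec$probe_currents) res$probe_currents else NULL,
                 probe_times = pt, probes = rec$probes,
                 peaks = if (rec$peaks) res$peaks else NULL,
                 final = final, config = config, stimuli = stimuli,
                 params = params, t0 = t0, duration = duration,
                 gate_range = c(res$gate_min, res$gate_max)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %dD N = %d, %g ms simulated", x$config$ndim,
              x$config$N, x$duration))
  if (!is.null(x$movie)) cat(sprintf(", %d frames", ncol(x$movie)))
  cat("\n")
  invisible(x)
}

#' One operator-splitting step
#'
#' Advances a `tissue_state` by a single Lie split step at time `t`:
#' explicit-Euler reaction (with stimulus currents where active) then the
#' diffusion propagator on V.
#'
#' @param state a `tissue_state`.
#' @param params an `ionic_params`.
#' @param stimuli list of [stimulus_spec()].
#' @param t current time, ms.
#' @param operator optional precomputed [diffusion_propagator()].
#' @return the advanced `tissue_state`.
#' @export
step_tissue <- function(state, params, stimuli = list(), t = 0,
                        operator = NULL) {
  config <- state$config
  res <- run_simulation(config, state, stimuli, config$dt, params,
                        record = list(movie_dt = 0), t0 = t)
  res$final
}

#' Propagation-failure check
#'
#' A stimulus is considered to have failed to propagate when no node beyond
#' `min_distance` cm from the stimulated region crosses `threshold` mV after
#' the stimulus onset.
#'
#' @param result a `sim_result` with a movie.
#' @param after time after which to look, ms.
#' @param min_distance distance from the stimulus region, cm.
#' @param threshold activation threshold, mV.
#' @return logical: `TRUE` if propagation failed.
#' @export
propagation_failed <- function(result, after = 0, min_distance = 1,
                               threshold = -40) {
  config <- result$config
  stim_nodes <- unique(unlist(lapply(result$stimuli, `[[`, "region")))
  xy <- node_coords(config)
  d2min <- rep(Inf, nrow(xy))
  for (s in stim_nodes)
    d2min <- pmin(d2min, (xy$x - xy$x[s])^2 + (xy$y - xy$y[s])^2)
  far <- sqrt(d2min) >= min_distance
  w <- result$movie_times >= after
  if (!any(far) || !any(w)) return(TRUE)
  max(result$movie[far, w, drop = FALSE]) < threshold
}

node_coords <- function(config) {
  if (config$ndim == 1) {
    tibble(node = seq_len(config$N), x = (seq_len(config$N) - 1) * config$dx,
           y = 0)
  } else {
    N <- config$N
    ix <- rep(seq_len(N), times = N); iy <- rep(seq_len(N), each = N)
    tibble(node = seq_len(N * N), x = (ix - 1) * config$dx,
           y = (iy - 1) * config$dx)
  }
}

#' Calibrate kappa for a target conduction velocity
#'
#' Bisection on the diffusion coefficient until a non-remodeled plane wave
#' propagates at `target_cv` (cm/s) within `tol`, measured between L/3 and
#' 2L/3 of the strand. Requires `beta = 0`.
#'
#' @param alpha real fractional order.
#' @param target_cv target conduction velocity, cm/s.
#' @param config_template a strand `tissue_config` providing geometry
#'   (its `kappa`/`order` are overridden).
#' @param params ionic parameters (default non-remodeled baseline).
#' @param bracket initial kappa bracket, cm^2/s.
#' @param tol CV tolerance, cm/s.
#' @param stim_amplitude pulse amplitude, pA/pF.
#' @return the calibrated kappa (cm^2/s, table convention).
#' @export
calibrate_kappa <- function(alpha, target_cv = 63, config_template = strand_config(),
                            params = ionic_params(), bracket = c(0.02, 40),
                            tol = 0.5, stim_amplitude = 40) {
  measure <- function(kappa) {
    cfg <- config_template
    cfg$kappa <- kappa
    cfg$order <- fractional_order(alpha, 0)
    strand_cv(cfg, params, membrane_state(), stim_amplitude = stim_amplitude,
              n_beats = 1)
  }
  lo <- bracket[1]; hi <- bracket[2]
  cv_lo <- measure(lo); cv_hi <- measure(hi)
  if (is.na(cv_lo)) cv_lo <- 0
  if (is.na(cv_hi) || cv_lo > target_cv || cv_hi < target_cv)
    abort("kappa bracket does not straddle the target CV")
  repeat {
    mid <- sqrt(lo * hi)
    cv <- measure(mid)
    if (is.na(cv)) cv <- 0
    if (abs(cv - target_cv) <= tol) return(mid)
    if (cv < target_cv) lo <- mid else hi <- mid
    if (hi / lo < 1.0005)
      return(mid)
  }
}

# plane-wave CV on a strand: stimulate the left edge, activation times at
# L/3 and 2L/3 on the requested beat
strand_cv <- function(config, params, init_state, stim_amplitude,
                      n_beats = 2, bcl = 1000, post = 500) {
  N <- config$N
  p1 <- as.integer(round(N / 3)); p2 <- as.integer(round(2 * N / 3))
  onsets <- seq(10, 10 + bcl * (n_beats - 1), by = bcl)
  stim <- stimulus_spec(region_left_edge(config), onsets, stim_amplitude)
  res <- run_simulation(config, init_state, list(stim),
                        max(onsets) + post, params,
                        record = list(movie_dt = 0, probes = c(p1, p2)))
  tt <- res$probe_times
  w <- tt > max(onsets)
  a1 <- activation_times(tt[w], res$probe_v[w, 1])
  a2 <- activation_times(tt[w], res$probe_v[w, 2])
  if (!length(a1) || !length(a2)) return(NA_real_)
  dtact <- a2[1] - a1[1]
  if (dtact <= 0) return(NA_real_)
  (p2 - p1) * config$dx / dtact * 1000
}
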