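#' Diastolic threshold of a tissue
#'
#' Bisection (1% relative precision) on the amplitude of a 2-ms pulse
#' delivered to the left edge of resting tissue, for the minimal amplitude
#' that elicits a propagated action potential (a node at least
#' `min_distance` cm from the stimulus crosses -40 mV).
#'
#' @param config a `tissue_config`.
#' @param params an `ionic_params`.
#' @param init resting `membrane_state` (or `tissue_state`).
#' @param stim_duration pulse duration, ms.
#' @param bracket amplitude bracket, pA/pF.
#' @param min_distance propagation distance criterion, cm.
#' @param window observation window after the pulse, ms.
#' @return the threshold amplitude, pA/pF.
#' @export
find_diastolic_threshold <- function(config, params, init = membrane_state(),
                                     stim_duration = 2, bracket = c(1, 120),
                                     min_distance = 1, window = 80) {
  probe <- if (config$ndim == 1) {
    as.integer(min(config$N, round(min_distance / config$dx) + 3))
  } else {
    ix <- as.integer(min(config$N, round(min_distance / config$dx) + 3))
    iy <- as.integer(round(config$N / 2))
    ix + (iy - 1L) * config$N
  }
  captures <- function(amp) {
    stim <- stimulus_spec(region_left_edge(config), 5, amp, stim_duration)
    res <- run_simulation(config, init, list(stim), 5 + window, params,
                          record = list(movie_dt = 0, probes = probe))
    max(res$probe_v[, 1]) > -40
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (captures(lo)) return(lo)
  if (!captures(hi)) abort("no capture at top of threshold bracket")
  while ((hi - lo) / hi > 0.01) {
    mid <- (lo + hi) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' S1-S2 cross-field stimulation episode
#'
#' Applies an S1 train (basic cycle length `s1_bcl`, `s1_count` beats) to the
#' left edge of a sheet, then a single premature S2 over the lower-left
#' quadrant at `coupling_interval` ms after the last S1 onset. The paced
#' S1 wavefronts are planar; the cross-field S2 can wrap around the
#' repolarization tail of the last S1 wave and start a rotor.
#'
#' @param config a 2-D `tissue_config`.
#' @param params an `ionic_params` (normally CAF-remodeled).
#' @param init initial `membrane_state`/`tissue_state` (paced-cell
#'   convention).
#' @param coupling_interval S2 delay after the last S1 onset, ms.
#' @param stim_amplitude pulse amplitude, pA/pF (2x diastolic threshold by
#'   protocol; pass the measured value).
#' @param s1_bcl S1 basic cycle length, ms.
#' @param s1_count number of S1 beats.
#' @param post_window simulated time after S2, ms.
#' @param movie_dt frame interval of the recorded movie, ms.
#' @param s1_edge_width width of the S1 edge region, nodes.
#' @return a `sim_result` with attributes `s1_times`, `s2_time`.
#' @export
run_crossfield <- function(config, params, init, coupling_interval,
                           stim_amplitude, s1_bcl = 400, s1_count = 2,
                           post_window = 800, movie_dt = 2,
                           s1_edge_width = 5) {
  stopifnot(config$ndim == 2)
  if (coupling_interval <= 0) abort("coupling_interval must be > 0")
  s1_times <- 10 + s1_bcl * (0:(s1_count - 1))
  s2_time <- max(s1_times) + coupling_interval
  if (s2_time <= max(s1_times))
    abort("S2 scheduled before completion of the S1 train")
  s1 <- stimulus_spec(region_left_edge(config, s1_edge_width), s1_times,
                      stim_amplitude)
  s2 <- stimulus_spec(region_lower_left_quadrant(config), s2_time,
                      stim_amplitude)
  res <- run_simulation(config, init, list(s1, s2), s2_time + post_window,
                        params, record = list(movie_dt = movie_dt))
  attr(res, "s1_times") <- s1_times
  attr(res, "s2_time") <- s2_time
  res
}

#' Midline repolarization time after the last S1
#'
#' Operational trigger reference of the cross-field protocol: the first time
#' after the last S1 at which the maximum voltage over the vertical midline
#' column falls below `threshold` mV (the "repolarization wave reaches half
#' of the domain" criterion).
#'
#' @param result a 2-D `sim_result` with a movie.
#' @param last_s1 time of the last S1 onset, ms.
#' @param threshold repolarization threshold, mV.
#' @return time in ms (`NA` if never reached within the movie).
#' @export
midline_repolarization_time <- function(result, last_s1,
                                        threshold = -70) {
  cfg <- result$config
  stopifnot(cfg$ndim == 2)
  N <- cfg$N
  mid_col <- as.integer(round(N / 2) + (0:(N - 1)) * N)
  vmax <- apply(result$movie[mid_col, , drop = FALSE], 2, max)
  tt <- result$movie_times
  # wait for the S1 wave to activate the midline first, then repolarize
  act <- which(tt > last_s1 & vmax > -40)[1]
  if (is.na(act)) return(NA_real_)
  rep_i <- which(seq_along(tt) > act & vmax < threshold)[1]
  if (is.na(rep_i)) return(NA_real_)
  tt[rep_i]
}

#' Rotor classification of an episode
#'
#' Computes the Hilbert phase movie, detects phase singularities, links them
#' into filaments, and reports the dominant (longest-lived) filament with
#' its rotation count and maximal tip displacement. "Sustained rotor" means
#' a persistent singularity whose filament completes at least `min_rotations`
#' rotations.
#'
#' @param result a 2-D `sim_result` with a movie.
#' @param after only frames at or after this time are analyzed, ms.
#' @param min_rotations sustained-rotor criterion (reference 2).
#' @param max_jump filament linking jump limit, cm per frame.
#' @return a list: `sustained`, `rotations`, `D` (cm), `filament` (tibble),
#'   `tips` (tibble), `n_filaments`.
#' @export
classify_rotor <- function(result, after = 0, min_rotations = 2,
                           max_jump = 0.3) {
  pm <- phase_movie(result, after = after)
  tips <- find_singularities_movie(pm)
  fils <- link_filaments(tips, max_jump = max_jump)
  if (!nrow(fils))
    return(list(sustained = FALSE, rotations = 0, D = 0,
                filament = fils, tips = tips, n_filaments = 0))
  counts <- table(fils$track_id)
  main_id <- names(counts)[which.max(counts)]
  main <- fils[fils$track_id == main_id, ]
  rot <- count_rotations(main, pm)
  list(sustained = rot >= min_rotations,
       rotations = rot, D = max_tip_displacement(main),
       filament = main, tips = tips,
       n_filaments = length(counts))
}

#' Vulnerable-window scan
#'
#' Runs one cross-field episode per coupling interval and classifies each as
#' sustaining a rotor (persistent phase singularity with >= 2 rotations) or
#' not. The vulnerable window is the difference between the maximum and
#' minimum sustaining coupling intervals (0 when none sustains).
#'
#' @param config a 2-D `tissue_config`.
#' @param params an `ionic_params`.
#' @param init initial state.
#' @param ci_values coupling intervals to scan, ms.
#' @param stim_amplitude pulse amplitude, pA/pF.
#' @param ... passed to [run_crossfield()].
#' @return a `vw_result`: list with `table` (tibble: `ci`, `sustained`,
#'   `rotations`, `D`), `ci_min`, `ci_max`, `vw`.
#' @export
vulnerable_window <- function(config, params, init, ci_values,
                              stim_amplitude, ...) {
  rows <- lapply(ci_values, function(ci) {
    res <- run_crossfield(config, params, init, ci, stim_amplitude, ...)
    cls <- classify_rotor(res, after = attr(res, "s2_time"))
    tibble(ci = ci, sustained = cls$sustained, rotations = cls$rotations,
           D = cls$D)
  })
  tab <- dplyr::bind_rows(rows)
  sus <- tab$ci[tab$sustained]
  out <- list(table = tab,
              ci_min = if (length(sus)) min(sus) else NA_real_,
              ci_max = if (length(sus)) max(sus) else NA_real_,
              vw = if (length(sus)) max(sus) - min(sus) else 0)
  class(out) <- "vw_result"
  out
}

#' @export
print.vw_result <- function(x, ...) {
  cat(sprintf("<vw_result> VW = %g ms over %d coupling intervals\n",
              x$vw, nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' S1-S2 restitution protocol on a strand
#'
#' A train of `s1_count` stimuli at `s1_bcl` ms is applied to the left end of
#' the strand, followed by one premature S2 per coupling interval. APD90 and
#' CV are measured at the probe located two thirds down the strand, provided
#' the S2 wave propagates. The S1 train is simulated once and each coupling
#' interval continues from the saved post-train state (the system is
#' deterministic, so this equals rerunning the full train).
#'
#' @param config a strand `tissue_config`.
#' @param params an `ionic_params`.
#' @param init initial state.
#' @param ci_values S2 coupling intervals, ms (descending scan conventional).
#' @param stim_amplitude pulse amplitude, pA/pF.
#' @param s1_bcl S1 basic cycle length, ms (reference 1000).
#' @param s1_count number of S1 beats (reference 10).
#' @param post_window time simulated after S2, ms.
#' @return a `restitution_curve` tibble: `ci`, `apd`, `cv`, `propagated`,
#'   with the S1 steady-state APD as attribute `s1_apd`.
#' @export
restitution_protocol <- function(config, params, init, ci_values,
                                 stim_amplitude, s1_bcl = 1000,
                                 s1_count = 10, post_window = 500) {
  stopifnot(config$ndim == 1)
  N <- config$N
  p1 <- as.integer(round(N / 3)); p2 <- as.integer(round(2 * N / 3))
  s1_times <- 10 + s1_bcl * (0:(s1_count - 1))
  last_s1 <- max(s1_times)
  edge <- region_left_edge(config)
  s1 <- stimulus_spec(edge, s1_times, stim_amplitude)
  # run the train up to the last S1 onset; snapshot the state there
  train <- run_simulation(config, init, list(s1), last_s1, params,
                          record = list(movie_dt = 0, probes = c(p1, p2)))
  # steady-state APD of the S1 train at the 2L/3 probe (second-to-last beat)
  tt <- train$probe_times
  acts <- activation_times(tt, train$probe_v[, 2])
  s1_apd <- if (length(acts) >= 2)
    apd90(tt, train$probe_v[, 2], acts[length(acts) - 1],
          next_activation = acts[length(acts)]) else NA_real_

  rows <- lapply(ci_values, function(ci) {
    s1_tail <- stimulus_spec(edge, last_s1, stim_amplitude)
    s2 <- stimulus_spec(edge, last_s1 + ci, stim_amplitude)
    res <- run_simulation(config, train$final, list(s1_tail, s2),
                          ci + post_window, params,
                          record = list(movie_dt = 0, probes = c(p1, p2)),
                          t0 = last_s1)
    ptt <- res$probe_times
    w <- ptt > last_s1 + ci
    a1 <- activation_times(ptt[w], res$probe_v[w, 1])
    a2 <- activation_times(ptt[w], res$probe_v[w, 2])
    if (!length(a2) || !length(a1)) {
      tibble(ci = ci, apd = NA_real_, cv = NA_real_, propagated = FALSE)
    } else {
      apd <- apd90(ptt, res$probe_v[, 2], a2[1])
      cv <- (p2 - p1) * config$dx / (a2[1] - a1[1]) * 1000
      tibble(ci = ci, apd = apd, cv = cv, propagated = TRUE)
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "s1_apd") <- s1_apd
  class(out) <- c("restitution_curve", class(out))
  out
}
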