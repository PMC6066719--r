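#' Activation times of a voltage trace
#'
#' Upward crossings of the activation threshold (default -40 mV) with a
#' refractory lockout; crossing times are linearly interpolated between
#' samples.
#'
#' @param t sample times, ms.
#' @param v voltages, mV.
#' @param threshold activation threshold, mV.
#' @param lockout minimal spacing between detected activations, ms.
#' @return numeric vector of activation times (possibly empty).
#' @export
activation_times <- function(t, v, threshold = -40, lockout = 50) {
  up <- which(v[-1] > threshold & v[-length(v)] <= threshold)
  if (!length(up)) return(numeric(0))
  tc <- t[up] + (threshold - v[up]) / (v[up + 1] - v[up]) * (t[up + 1] - t[up])
  keep <- c(TRUE, diff(tc) >= lockout)
  while (!all(keep)) {
    tc <- tc[keep]
    keep <- c(TRUE, diff(tc) >= lockout)
  }
  tc
}

#' Action potential duration at 90% repolarization
#'
#' APD90 is the time from the activation upstroke until V first falls below
#' `peak - 0.9 * (peak - V_rest)`, where `V_rest` is the pre-upstroke
#' diastolic potential (the minimum over the `rest_window` ms preceding the
#' activation — the minimum, not the mean, so the rising stimulus/electrotonic
#' foot inside the window cannot bias the reference) and `peak` the maximum V
#' of the beat. The downward crossing is linearly interpolated. Invariant
#' under time shifts and affine voltage maps.
#'
#' @param t sample times, ms.
#' @param v voltages, mV.
#' @param activation activation time of the beat, ms (see
#'   [activation_times()]).
#' @param next_activation end of the beat window, ms (`Inf` = trace end).
#' @param rest_window length of the pre-upstroke window defining `V_rest`,
#'   ms.
#' @return APD90 in ms, or `NA` if the AP has not repolarized within the
#'   window (flagged with a warning).
#' @export
apd90 <- function(t, v, activation, next_activation = Inf, rest_window = 10) {
  pre <- t >= activation - rest_window & t < activation
  if (!any(pre)) pre <- t < activation
  v_rest <- min(v[pre])
  w <- t >= activation & t < next_activation
  ts <- t[w]; vs <- v[w]
  peak_i <- which.max(vs)
  thr <- vs[peak_i] - 0.9 * (vs[peak_i] - v_rest)
  dn <- which(vs[-1] < thr & vs[-length(vs)] >= thr)
  dn <- dn[dn >= peak_i]
  if (!length(dn)) {
    warn("action potential not repolarized within the beat window")
    return(NA_real_)
  }
  i <- dn[1]
  tc <- ts[i] + (thr - vs[i]) / (vs[i + 1] - vs[i]) * (ts[i + 1] - ts[i])
  tc - activation
}

#' Conduction velocity between two probe nodes
#'
#' CV is the probe separation divided by the difference of the activation
#' times of the same wavefront at the two probes. By convention the probes
#' sit at one third and two thirds of the strand length.
#'
#' @param result a `sim_result` with at least two probe traces.
#' @param beat which activation to use (`"last"` or an index).
#' @param after only consider activations after this time, ms.
#' @return CV in cm/s; `NA` if either probe was not activated.
#' @export
conduction_velocity <- function(result, beat = 1, after = 0) {
  if (is.null(result$probe_v) || length(result$probes) < 2)
    abort("conduction_velocity needs two recorded probes")
  cfg <- result$config
  tt <- result$probe_times
  w <- tt >= after
  a1 <- activation_times(tt[w], result$probe_v[w, 1])
  a2 <- activation_times(tt[w], result$probe_v[w, 2])
  if (identical(beat, "last")) beat <- min(length(a1), length(a2))
  if (length(a1) < beat || length(a2) < beat) return(NA_real_)
  if (length(a1) != length(a2))
    warn("probes saw different activation counts; wave association may be off")
  dt_act <- a2[beat] - a1[beat]
  if (dt_act <= 0) {
    warn("non-monotone activation order between probes")
    return(NA_real_)
  }
  dist <- abs(diff(result$probes[1:2])) * cfg$dx
  dist / dt_act * 1000
}

#' APD dispersion profile of a strand
#'
#' Per-node APD90 for one beat, the global dispersion (range over the
#' strand) and the local dispersion (minimum APD minus local APD, <= 0
#' everywhere). Nodes within `edge_exclude` nodes of either boundary are
#' excluded to suppress mirror-boundary artifacts.
#'
#' @param result a 1-D `sim_result` with a movie.
#' @param beat_onset time of the measured beat's stimulus, ms.
#' @param edge_exclude boundary nodes excluded per side.
#' @return an `apd_profile`: tibble (`node`, `x`, `apd`, `local_dapd`) with
#'   attribute `global_dapd`.
#' @export
apd_dispersion <- function(result, beat_onset = 0, edge_exclude = 5) {
  if (is.null(result$movie)) abort("apd_dispersion needs a recorded movie")
  cfg <- result$config
  stopifnot(cfg$ndim == 1)
  keep <- (edge_exclude + 1):(cfg$N - edge_exclude)
  tt <- result$movie_times
  apds <- vapply(keep, function(i) {
    v <- result$movie[i, ]
    acts <- activation_times(tt, v)
    acts <- acts[acts >= beat_onset]
    if (!length(acts)) return(NA_real_)
    apd90(tt, v, acts[1])
  }, numeric(1))
  if (anyNA(apds)) {
    warn("partial propagation: dispersion profile restricted to activated nodes")
    keep <- keep[!is.na(apds)]
    apds <- apds[!is.na(apds)]
  }
  prof <- tibble(node = keep, x = (keep - 1) * cfg$dx, apd = apds,
                 local_dapd = min(apds) - apds)
  attr(prof, "global_dapd") <- max(apds) - min(apds)
  class(prof) <- c("apd_profile", class(prof))
  prof
}

#' @export
print.apd_profile <- function(x, ...) {
  cat(sprintf("<apd_profile> %d nodes, global dAPD = %.2f ms\n",
              nrow(x), attr(x, "global_dapd")))
  NextMethod()
}

#' Per-node peak current profiles
#'
#' Peak magnitudes of I_Na, I_to, I_Kur and I_CaL reached at each node
#' during the run (requires `record = list(peaks = TRUE)`).
#'
#' @param result a `sim_result` with peak tracking enabled.
#' @return a tidy tibble (`node`, `x`, `current`, `peak`), peaks in pA/pF.
#' @export
peak_current_profiles <- function(result) {
  if (is.null(result$peaks)) abort("per-node current peaks were not recorded")
  xy <- node_coords(result$config)
  cur <- c("I_Na", "I_to", "I_Kur", "I_CaL")
  out <- lapply(seq_along(cur), function(i) {
    tibble(node = xy$node, x = xy$x, current = cur[i],
           peak = as.numeric(result$peaks[i, ]))
  })
  dplyr::bind_rows(out)
}
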