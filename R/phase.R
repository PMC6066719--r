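#' Analytic signal via the Fourier transform
#'
#' Standard frequency-domain construction: positive frequencies doubled,
#' negative zeroed; the imaginary part is the Hilbert transform of the
#' (de-meaned) input.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert phase movie of a voltage movie
#'
#' For each node the temporal mean is subtracted, the analytic signal is
#' computed over the node's full time series, and the phase at each frame is
#' `atan2(Im(analytic), V - mean(V))`, in `(-pi, pi]`. Nodes with constant
#' traces have undefined phase and are masked (`NA`).
#'
#' @param x a `sim_result` with a movie, or a numeric matrix
#'   (nodes x frames).
#' @param times frame times, ms (taken from the `sim_result` if omitted).
#' @param config a 2-D `tissue_config` describing the node layout (from the
#'   `sim_result` if omitted).
#' @param after drop frames before this time, ms, before the transform.
#' @return a `phase_movie`: list with `phase` (nodes x frames matrix),
#'   `times`, `nx`, `ny`, `dx`.
#' @export
phase_movie <- function(x, times = NULL, config = NULL, after = -Inf) {
  if (inherits(x, "sim_result")) {
    if (is.null(x$movie)) abort("sim_result has no recorded movie")
    times <- x$movie_times
    config <- x$config
    x <- x$movie
  }
  if (is.null(times) || is.null(config))
    abort("times and config are required for matrix input")
  keep <- times >= after
  x <- x[, keep, drop = FALSE]
  times <- times[keep]
  ph <- matrix(NA_real_, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    if (diff(range(v)) < 1e-9) next  # constant trace: phase undefined
    vz <- v - mean(v)
    a <- analytic_signal(vz)
    ph[i, ] <- atan2(Im(a), vz)
  }
  structure(list(phase = ph, times = times,
                 nx = config$N, ny = if (config$ndim == 2) config$N else 1L,
                 dx = config$dx),
            class = "phase_movie")
}

wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

#' Phase singularities in a single phase frame
#'
#' Topological-charge detection: the wrapped phase differences are summed
#' around every 2x2 plaquette; windings of `|sum| >= pi * (2 - eps)` mark a
#' phase singularity at the plaquette center, with charge `sign(sum)`.
#'
#' @param frame phase values: an `nx x ny` matrix (or vector of length
#'   `nx * ny`).
#' @param nx,ny grid dimensions.
#' @param dx node spacing, cm.
#' @param eps winding-threshold tolerance.
#' @return a tibble (`x`, `y`, `charge`), possibly empty.
#' @export
find_singularities <- function(frame, nx, ny, dx, eps = 0.1) {
  p <- matrix(frame, nx, ny)
  if (anyNA(p)) p[is.na(p)] <- 0
  d_right <- wrap_pi(p[-1, , drop = FALSE] - p[-nx, , drop = FALSE]) # (nx-1) x ny
  d_up <- wrap_pi(p[, -1, drop = FALSE] - p[, -ny, drop = FALSE])    # nx x (ny-1)
  winding <- d_right[, -ny, drop = FALSE] +     # bottom edge ->
    d_up[-1, , drop = FALSE] -                  # right edge ^
    d_right[, -1, drop = FALSE] -               # top edge <-
    d_up[-nx, , drop = FALSE]                   # left edge v
  hit <- which(abs(winding) >= pi * (2 - eps), arr.ind = TRUE)
  if (!nrow(hit)) return(tibble(x = numeric(0), y = numeric(0),
                                charge = numeric(0)))
  tibble(x = (hit[, 1] - 0.5) * dx, y = (hit[, 2] - 0.5) * dx,
         charge = sign(winding[hit]))
}

#' Phase singularities of every frame of a phase movie
#'
#' @param pm a [phase_movie()].
#' @param eps winding-threshold tolerance.
#' @return a tibble (`frame`, `t`, `x`, `y`, `charge`).
#' @export
find_singularities_movie <- function(pm, eps = 0.1) {
  stopifnot(inherits(pm, "phase_movie"))
  rows <- lapply(seq_along(pm$times), function(f) {
    tips <- find_singularities(pm$phase[, f], pm$nx, pm$ny, pm$dx, eps)
    if (nrow(tips)) {
      tips$frame <- f
      tips$t <- pm$times[f]
    }
    tips
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(tibble(frame = integer(0), t = numeric(0),
                                x = numeric(0), y = numeric(0),
                                charge = numeric(0)))
  out[, c("frame", "t", "x", "y", "charge")]
}

#' Link per-frame singularities into filaments
#'
#' Nearest-neighbor association between consecutive frames with a maximum
#' jump of `max_jump` cm per frame; unmatched tips start or end tracks. The
#' filament is the rotor tip trajectory in (x, y, t).
#'
#' @param tips tibble from [find_singularities_movie()].
#' @param max_jump association limit, cm per frame.
#' @return a `filament_set` tibble (`track_id`, `frame`, `t`, `x`, `y`,
#'   `charge`), ordered by track and time.
#' @export
link_filaments <- function(tips, max_jump = 0.3) {
  empty <- tibble(track_id = integer(0), frame = integer(0), t = numeric(0),
                  x = numeric(0), y = numeric(0), charge = numeric(0))
  class(empty) <- c("filament_set", class(empty))
  if (!nrow(tips)) return(empty)
  frames <- sort(unique(tips$frame))
  next_id <- 0L
  tips$track_id <- NA_integer_
  prev_idx <- integer(0)
  for (f in frames) {
    cur_idx <- which(tips$frame == f)
    assigned <- rep(FALSE, length(cur_idx))
    if (length(prev_idx)) {
      # greedy closest-pair association
      dmat <- outer(seq_along(prev_idx), seq_along(cur_idx),
                    Vectorize(function(i, j) {
                      sqrt((tips$x[prev_idx[i]] - tips$x[cur_idx[j]])^2 +
                           (tips$y[prev_idx[i]] - tips$y[cur_idx[j]])^2)
                    }))
      used_prev <- rep(FALSE, length(prev_idx))
      repeat {
        dmin <- min(dmat)
        if (!is.finite(dmin) || dmin > max_jump) break
        w <- which(dmat == dmin, arr.ind = TRUE)[1, ]
        tips$track_id[cur_idx[w[2]]] <- tips$track_id[prev_idx[w[1]]]
        assigned[w[2]] <- TRUE
        used_prev[w[1]] <- TRUE
        dmat[w[1], ] <- Inf
        dmat[, w[2]] <- Inf
      }
    }
    for (j in which(!assigned)) {
      next_id <- next_id + 1L
      tips$track_id[cur_idx[j]] <- next_id
    }
    prev_idx <- cur_idx
  }
  out <- tips[order(tips$track_id, tips$frame),
              c("track_id", "frame", "t", "x", "y", "charge")]
  class(out) <- c("filament_set", class(out))
  out
}

#' Maximal tip displacement D
#'
#' The maximum Euclidean distance between any two points of a filament,
#' treating all points as coplanar (time ignored). Quantifies the spatial
#' stability of a rotor: small D = a rotor pinned near a stable core.
#'
#' @param filament tibble with `x`, `y` columns (one track).
#' @return D in cm (0 for a single point).
#' @export
max_tip_displacement <- function(filament) {
  if (!nrow(filament)) abort("empty filament")
  if (nrow(filament) == 1) return(0)
  max(stats::dist(cbind(filament$x, filament$y)))
}

#' Rotation count of a filament
#'
#' Unwraps the phase at the node nearest to the filament's temporal-mean
#' position and returns the total phase advance over the filament lifetime
#' divided by 2*pi. If that node's phase is masked, the nearest unmasked
#' node is used.
#'
#' @param filament one track (tibble with `frame`, `t`, `x`, `y`).
#' @param pm the [phase_movie()] the filament was detected in.
#' @return number of rotations (>= 0; 0 for single-frame filaments).
#' @export
count_rotations <- function(filament, pm) {
  if (nrow(filament) < 2) return(0)
  cx <- mean(filament$x); cy <- mean(filament$y)
  ix <- pmin(pmax(round(cx / pm$dx) + 1, 1), pm$nx)
  iy <- pmin(pmax(round(cy / pm$dx) + 1, 1), pm$ny)
  node <- ix + (iy - 1) * pm$nx
  frames <- min(filament$frame):max(filament$frame)
  ph <- pm$phase[node, frames]
  if (anyNA(ph)) {
    # fall back to nearest node with defined phase
    coords <- node_coords(list(ndim = if (pm$ny > 1) 2L else 1L, N = pm$nx,
                               dx = pm$dx))
    ok <- which(!is.na(pm$phase[, frames[1]]))
    if (!length(ok)) return(0)
    d2 <- (coords$x[ok] - cx)^2 + (coords$y[ok] - cy)^2
    node <- ok[which.min(d2)]
    ph <- pm$phase[node, frames]
  }
  dph <- wrap_pi(diff(ph))
  abs(sum(dph)) / (2 * pi)
}

#' Export tips or filaments to CSV
#'
#' @param tips tibble of tips or a `filament_set`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tips_csv <- function(tips, path) {
  utils::write.csv(as.data.frame(tips), path, row.names = FALSE)
  invisible(path)
}
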