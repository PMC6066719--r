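#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a paced-cell trace
#'
#' @param x a `pace_trace`.
#' @param ... unused.
#' @return the trace as a tibble (`time`, `V`, `beat`).
#' @method tidy pace_trace
#' @export
tidy.pace_trace <- function(x, ...) {
  tr <- x$trace
  tr$beat <- findInterval(tr$time, x$onsets)
  tr
}

#' One-row summary of a paced-cell run
#'
#' `apd90` and `v_rest` are measured on the last beat: the diastolic
#' potential is taken immediately before the final stimulus and the APD at
#' 90% repolarization from the final upstroke.
#'
#' @param x a `pace_trace`.
#' @param ... unused.
#' @return tibble with `apd90` (ms), `v_rest` (mV), `v_peak` (mV), `n_beats`,
#'   `captured`.
#' @method glance pace_trace
#' @export
glance.pace_trace <- function(x, ...) {
  tt <- x$trace$time; v <- x$trace$V
  last <- max(x$onsets)
  pre <- tt >= last - 5 & tt < last
  v_rest <- mean(v[pre])
  acts <- activation_times(tt, v)
  last_act <- acts[length(acts)]
  tibble(apd90 = apd90(tt, v, last_act),
         v_rest = v_rest,
         v_peak = max(v[tt >= last]),
         n_beats = length(acts),
         captured = x$captured)
}

#' Tidy a simulation movie into long format
#'
#' @param x a `sim_result` with a movie.
#' @param ... unused.
#' @return tibble (`node`, `x`, `y`, `time`, `V`).
#' @method tidy sim_result
#' @export
tidy.sim_result <- function(x, ...) {
  if (is.null(x$movie)) abort("sim_result has no recorded movie")
  xy <- node_coords(x$config)
  nfr <- ncol(x$movie)
  tibble(node = rep(xy$node, nfr),
         x = rep(xy$x, nfr),
         y = rep(xy$y, nfr),
         time = rep(x$movie_times, each = nrow(x$movie)),
         V = as.numeric(x$movie))
}

#' One-row summary of a tissue simulation
#'
#' @param x a `sim_result`.
#' @param ... unused.
#' @return tibble with geometry, order, kappa and voltage range.
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, ...) {
  tibble(ndim = x$config$ndim, N = x$config$N, dx = x$config$dx,
         dt = x$config$dt, kappa = x$config$kappa,
         alpha = x$config$order$alpha, beta = x$config$order$beta,
         duration = x$duration,
         v_min = if (!is.null(x$movie)) min(x$movie) else NA_real_,
         v_max = if (!is.null(x$movie)) max(x$movie) else NA_real_)
}

#' Summary of a vulnerable-window scan
#'
#' @param x a `vw_result`.
#' @param ... unused.
#' @return tibble with `vw`, `ci_min`, `ci_max`, `n_sustained`, `n_scanned`.
#' @method glance vw_result
#' @export
glance.vw_result <- function(x, ...) {
  tibble(vw = x$vw, ci_min = x$ci_min, ci_max = x$ci_max,
         n_sustained = sum(x$table$sustained), n_scanned = nrow(x$table))
}

#' @method tidy vw_result
#' @export
tidy.vw_result <- function(x, ...) x$table
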