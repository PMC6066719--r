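#' @import ggplot2
NULL

#' Plot a paced-cell voltage trace
#'
#' @param object a `pace_trace`.
#' @param last_ms show only the final `last_ms` ms (default: whole trace).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pace_trace
#' @export
autoplot.pace_trace <- function(object, last_ms = NULL, ...) {
  tr <- object$trace
  if (!is.null(last_ms)) tr <- tr[tr$time >= max(tr$time) - last_ms, ]
  ggplot(tr, aes(x = .data$time, y = .data$V)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = "V (mV)") +
    theme_minimal()
}

#' Space-time (1-D) or snapshot (2-D) view of a simulation
#'
#' Strand results are drawn as a space-time voltage map; sheet results as a
#' voltage snapshot at `frame_time`.
#'
#' @param object a `sim_result` with a movie.
#' @param frame_time snapshot time for 2-D results, ms (default: last
#'   frame).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sim_result
#' @export
autoplot.sim_result <- function(object, frame_time = NULL, ...) {
  if (is.null(object$movie)) abort("sim_result has no recorded movie")
  if (object$config$ndim == 1) {
    d <- tidy(object)
    ggplot(d, aes(x = .data$time, y = .data$x, fill = .data$V)) +
      geom_raster() +
      scale_fill_viridis_c(name = "V (mV)") +
      labs(x = "time (ms)", y = "x (cm)") +
      theme_minimal()
  } else {
    ft <- frame_time %||% max(object$movie_times)
    f <- which.min(abs(object$movie_times - ft))
    d <- tidy(object)
    d <- d[d$time == object$movie_times[f], ]
    ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$V)) +
      geom_raster() +
      scale_fill_viridis_c(name = "V (mV)") +
      coord_equal() +
      labs(x = "x (cm)", y = "y (cm)",
           title = sprintf("t = %.0f ms", object$movie_times[f])) +
      theme_minimal()
  }
}

#' Plot restitution curves
#'
#' @param object a `restitution_curve`.
#' @param ... unused.
#' @return a ggplot with APD and CV panels against the coupling interval.
#' @method autoplot restitution_curve
#' @export
autoplot.restitution_curve <- function(object, ...) {
  d <- object[object$propagated, ]
  long <- dplyr::bind_rows(
    tibble(ci = d$ci, value = d$apd, which = "APD90 (ms)"),
    tibble(ci = d$ci, value = d$cv, which = "CV (cm/s)"))
  ggplot(long, aes(x = .data$ci, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~which, scales = "free_y") +
    labs(x = "coupling interval (ms)", y = NULL) +
    theme_minimal()
}

#' Plot rotor tip filaments in the (x, y) plane
#'
#' The temporal-mean tip position (the rotor core) is marked in red; the two
#' farthest points of the trajectory (distance D) in black.
#'
#' @param object a `filament_set` (one or more tracks).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot filament_set
#' @export
autoplot.filament_set <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$x, y = .data$y,
                          group = .data$track_id)) +
    geom_path(alpha = 0.7) +
    coord_equal() +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
  main <- names(which.max(table(object$track_id)))
  tr <- object[object$track_id == main, ]
  if (nrow(tr) >= 2) {
    dm <- as.matrix(stats::dist(cbind(tr$x, tr$y)))
    ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    p <- p +
      annotate("point", x = mean(tr$x), y = mean(tr$y), colour = "red",
               size = 2) +
      annotate("point", x = tr$x[ij], y = tr$y[ij], colour = "black",
               shape = 4, size = 2)
  }
  p
}

#' Phase map snapshot
#'
#' @param pm a `phase_movie`.
#' @param frame frame index.
#' @return a ggplot of the phase field with detected singularities overlaid.
#' @export
plot_phase_frame <- function(pm, frame = 1) {
  stopifnot(inherits(pm, "phase_movie"))
  d <- tibble(x = rep((0:(pm$nx - 1)) * pm$dx, pm$ny),
              y = rep((0:(pm$ny - 1)) * pm$dx, each = pm$nx),
              phase = pm$phase[, frame])
  tips <- find_singularities(pm$phase[, frame], pm$nx, pm$ny, pm$dx)
  p <- ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$phase)) +
    geom_raster() +
    scale_fill_gradientn(colours = c("#2166ac", "#f7f7f7", "#b2182b",
                                     "#2166ac"), name = "phase") +
    coord_equal() + labs(x = "x (cm)", y = "y (cm)") + theme_minimal()
  if (nrow(tips))
    p <- p + geom_point(data = tips, aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, shape = 21, fill = "white")
  p
}
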