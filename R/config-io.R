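RUN_CONFIG_SCHEMA <- list(
  grid = c("ndim", "N", "L", "dx", "dt"),
  order = c("alpha", "beta"),
  kappa = c("value", "k_power_ref"),
  cell = c("remodeled", "ACh_nM"),
  protocol = c("kind", "bcl", "duration", "s1_bcl", "s1_count",
               "coupling_interval", "ci_min", "ci_max", "ci_step",
               "stim_amplitude", "stim_duration", "post_window"),
  recording = c("movie_dt", "probes", "peaks"),
  output = c("dir", "prefix")
)

#' Read and validate a run configuration
#'
#' Run configurations are YAML files with sections `grid`, `order`, `kappa`,
#' `cell`, `protocol`, `recording`, `output`. Unknown sections or keys are
#' rejected.
#'
#' @param path YAML file.
#' @return the validated configuration list, class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  bad_sec <- setdiff(names(cfg), names(RUN_CONFIG_SCHEMA))
  if (length(bad_sec))
    abort(paste("unknown config sections:", paste(bad_sec, collapse = ", ")))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), RUN_CONFIG_SCHEMA[[sec]])
    if (length(bad))
      abort(sprintf("unknown keys in section '%s': %s", sec,
                    paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

#' Write a resolved run configuration
#'
#' @param cfg a `run_config` (or plain list following the schema).
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(unclass(cfg))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build package objects from a run configuration
#'
#' @param cfg a `run_config`.
#' @return list with `config` (tissue config, if `grid` present) and
#'   `params` (ionic parameters).
#' @export
from_run_config <- function(cfg) {
  params <- ionic_params()
  cell <- cfg$cell %||% list()
  if (isTRUE(cell$remodeled))
    params <- apply_caf_remodeling(params, ACh_nM = cell$ACh_nM %||% 5)
  else if (!is.null(cell$ACh_nM))
    params$values["ACh_nM"] <- cell$ACh_nM
  config <- NULL
  if (!is.null(cfg$grid)) {
    ord <- fractional_order(cfg$order$alpha %||% 2, cfg$order$beta %||% 0)
    kap <- cfg$kappa$value %||% 0.40
    kref <- cfg$kappa$k_power_ref %||% 0.5
    g <- cfg$grid
    config <- if ((g$ndim %||% 1) == 1) {
      strand_config(L = g$L %||% 2, N = g$N %||% 128, dt = g$dt %||% 0.01,
                    kappa = kap, order = ord, k_power_ref = kref)
    } else {
      sheet_config(N = g$N %||% 128, dx = g$dx %||% 0.03215,
                   dt = g$dt %||% 0.01, kappa = kap, order = ord,
                   k_power_ref = kref)
    }
  }
  list(config = config, params = params)
}

#' Write a voltage trace as two-column CSV
#'
#' @param trace tibble/data frame with `time` and `V` columns (e.g.
#'   `pace_trace$trace`).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("time", "V")], path, row.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param path CSV file.
#' @return a tibble with `time`, `V`.
#' @export
read_trace_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
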