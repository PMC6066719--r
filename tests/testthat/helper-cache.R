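# Lazily computed shared objects (deterministic; cached per test run).
.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

base_params <- function() memo("base", ionic_params())
caf_params <- function() memo("caf", apply_caf_remodeling(ionic_params()))

# tissue initial condition: CAF cell paced 60 s at BCL 400 ms
caf_init_400 <- function() memo("caf_init_400", {
  pace_cell(caf_params(), bcl = 400, duration = 60000,
            stim_amplitude = 2 * cell_thr())$final_state
})

cell_thr <- function() memo("cell_thr", find_cell_threshold(base_params()))

# paced single-cell runs for the single-cell acceptance block
paced_60s <- function(params, key) memo(key, {
  pace_cell(params, bcl = 1000, duration = 60000,
            stim_amplitude = 2 * cell_thr())
})

# diastolic threshold of the reference strand (non-remodeled, classical)
strand_thr <- function() memo("strand_thr", {
  find_diastolic_threshold(strand_config(kappa = 0.40), base_params())
})
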