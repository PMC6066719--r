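# cardiofrac

Rotor dynamics in chronically fibrillating atria depend not only on ionic
(electrical) remodeling but on the *structure* of the myocardium — a
discrete, heterogeneous medium that the standard monodomain equation
idealizes as a homogeneous continuum. `cardiofrac` implements a
generalization in which the spatial coupling is a **complex fractional-order
diffusion operator**: a complex-conjugate pair of spectral fractional
Laplacians,

    dV/dt = kappa * (Hx^gamma V + Hy^gamma V) + I_ion / C
    Hx^gamma = -1/2 [ (-d2/dx2)^(gamma/2) + (-d2/dx2)^(conj(gamma)/2) ],
    gamma = alpha + j*beta,

acting on Fourier modes as the real multiplier
`s(k) = -|k|^alpha * cos(beta * ln|k|)`. The real part `alpha` is the
fractal dimension of the conducting medium (`alpha = 2, beta = 0` is
classical diffusion); the imaginary part `beta` is the log-periodic
correction produced by discrete scale invariance. Lowering `alpha` and
raising `beta` emulate increasing structural heterogeneity: conduction
slows, action potentials shorten, the vulnerable window to reentry widens
and rotor tips meander over larger areas.

The reaction term is the Courtemanche–Ramirez–Nattel human atrial cell
model (compiled C++ kernel) with chronic-AF conductance remodeling
(`I_to`, `I_CaL` ×0.65, `I_Kur` ×0.49, `I_K1` ×2.1) and an
acetylcholine-activated K⁺ current (5 nM by default). On top of the tissue
integrator (operator splitting: explicit-Euler reaction + exact spectral
diffusion propagator with mirror/zero-flux boundaries) the package provides

* stimulation protocols: diastolic-threshold search, S1–S2 cross-field
  rotor induction, S1–S2 restitution, vulnerable-window scans;
* biomarkers: activation times, APD90, conduction velocity, global/local
  APD dispersion, per-node peak-current profiles;
* rotor analysis: Hilbert phase maps, phase-singularity detection
  (topological charge on 2×2 plaquettes), filament linking, rotation
  counts and the maximal tip displacement `D`;
* tidy interfaces throughout: results are tibbles, fitted objects have
  `tidy()`/`glance()`/`autoplot()` methods;
* a command-line driver (`exec/cardiofrac`) with subcommands
  `single-cell | strand | sheet | restitution | vw | phase`.

## Worked example

Sixty seconds of 1-Hz pacing, baseline vs chronic-AF remodeled cell:

```r
library(cardiofrac)

base <- ionic_params()
caf  <- apply_caf_remodeling(base)      # x0.65, x0.49, x2.1 + 5 nM ACh

amp <- 2 * find_cell_threshold(base)    # 2-ms pulses, twice threshold
glance(pace_cell(base, bcl = 1000, duration = 60000, stim_amplitude = amp))
#> # A tibble: 1 x 5
#>   apd90 v_rest v_peak n_beats captured
#>   <dbl>  <dbl>  <dbl>   <int>    <dbl>
#> 1  293.  -81.0   26.7      60        1
glance(pace_cell(caf,  bcl = 1000, duration = 60000, stim_amplitude = amp))
#> # A tibble: 1 x 5
#>   apd90 v_rest v_peak n_beats captured
#>   <dbl>  <dbl>  <dbl>   <int>    <dbl>
#> 1  95.5  -84.9   24.6      60        1
```

Electrical remodeling shortens the action potential from ~293 ms to
~96 ms and hyperpolarizes the diastolic potential from −81.0 to −84.9 mV —
the substrate that lets a rotor fit inside a few centimetres of atrium.

A remodeled strand conducting under classical vs complex-order diffusion:

```r
cfg0 <- strand_config(kappa = 0.40, order = fractional_order(2, 0))
cfgb <- strand_config(kappa = 0.40, order = fractional_order(2, 0.28))
init <- pace_cell(caf, bcl = 400, duration = 60000,
                  stim_amplitude = amp)$final_state   # tissue initial state

cv_of <- function(cfg) {
  thr  <- find_diastolic_threshold(cfg, caf, init)
  stim <- stimulus_spec(region_left_edge(cfg), c(10, 1010), 2 * thr)
  res  <- run_simulation(cfg, init, list(stim), 1510, caf,
                         record = list(movie_dt = 0,
                                       probes = round(cfg$N * c(1, 2) / 3)))
  conduction_velocity(res, beat = 1, after = 1010)
}
cv_of(cfg0)   # 60.24 cm/s  (classical diffusion)
cv_of(cfgb)   # 39.05 cm/s  (beta = 0.28: same kappa, slower conduction)
```

The same `beta` that slows conduction also destabilizes rotors: see
`run_crossfield()`, `classify_rotor()` and `vulnerable_window()`, or the
CLI (`cardiofrac sheet --caf --beta 0.28 --ci-ms 150 --out out/`).

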