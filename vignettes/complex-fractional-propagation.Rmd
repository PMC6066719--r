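---
title: "Complex fractional-order diffusion modeling of atrial propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex fractional-order diffusion modeling of atrial propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`cardiofrac` simulates atrial action-potential propagation with a
space-fractional monodomain equation

$$\frac{\partial V}{\partial t} \;=\;
  \kappa\,(H_x^{\gamma} V + H_y^{\gamma} V)\; +\; \frac{1}{C}\,I_{\mathrm{ion}},$$

where the spatial coupling is not the classical Laplacian but a
*complex-conjugate pair* of spectral fractional Laplacians,

$$H_x^{\gamma} \;=\; -\tfrac12\Big[\big(-\partial_x^2\big)^{\gamma/2}
  + \big(-\partial_x^2\big)^{\bar\gamma/2}\Big],
  \qquad \gamma = \alpha + j\beta .$$

On Fourier modes the pair collapses to multiplication by the *real* symbol

$$s(k) \;=\; -\,|k|^{\alpha}\,\cos\!\big(\beta \ln |k|\big),$$

so the operator maps real fields to real fields by construction. The real
part $\alpha \in (1, 2]$ plays the role of a fractal dimension of the
conducting medium (with $\alpha = 2$, $\beta = 0$ recovering standard
diffusion in a continuous, homogeneous tissue); $\beta \ge 0$ is a
log-periodic correction that arises when the medium is self-similar only at
discrete magnification scales (discrete scale invariance). Decreasing
$\alpha$ and increasing $\beta$ both act as knobs for structural
heterogeneity: they slow conduction, shorten the action potential and
destabilize reentrant waves, without touching a single ionic parameter.

The reaction term is the Courtemanche–Ramirez–Nattel human atrial membrane
model (21 state variables: $V$, 15 gates, three intracellular
concentrations, two sarcoplasmic-reticulum calcium pools), transcribed from
the published parameterisation. Chronic-AF electrical remodeling is applied
as conductance scalings ($g_{to}, g_{CaL} \times 0.65$, $g_{Kur} \times
0.49$, $g_{K1} \times 2.1$) plus an acetylcholine-activated potassium
current (Kneller-type dose–response, default 5 nM agonist).

## Numerical scheme

* **Operator splitting.** Each step of length $\Delta t$ advances the
  reaction by forward (explicit) Euler at every node, then applies the
  diffusion propagator to the voltage field only. Lie (first-order)
  splitting is the default; Strang splitting is available via
  `splitting = "strang"`. At the reference $\Delta t = 0.01$ ms the
  splitting error is negligible against the Euler reaction error, which is
  why plain Lie is the default.
* **Spectral diffusion with zero-flux boundaries.** The field is extended
  by an even (half-sample) mirror to length $2N$ per axis, transformed,
  multiplied by $\exp(\kappa\, s(k)\, \Delta t)$, inverse-transformed and
  restricted. This is the spectral-Neumann convention: edge stimulation
  produces plane waves rather than periodic wrap-around. Because the
  propagator is exact, the diffusion substep is unconditionally stable
  whenever $s(k) \le 0$ on all resolved modes, and the spatial mean is
  conserved exactly ($s(0) = 0$ by the removable-singularity convention).
  Internally the per-axis propagator is a dense $N \times N$ matrix applied
  by BLAS; for the grids used here ($N \le 128$) this is as fast as FFTs
  per step and simpler to reason about.
* **Stability in $\beta$.** $s(k) \le 0$ requires $\cos(\beta \ln k) \ge 0$
  for every resolved $k$, giving
  $\beta_{\max} = (\pi/2) / \max_k |\ln k|$ (`max_stable_beta()`). With $k$
  in rad/cm this is $\approx 0.343$ on the 321.5-µm sheet grid and
  $\approx 0.296$ on the 156-µm strand grid — the operating range
  $\beta \le 0.28$ is admissible on both. Constructing a propagator beyond
  the bound is refused with an error naming the offending $\beta$.
* **Reaction kernel.** The Courtemanche right-hand side is compiled (C++)
  and uses a voltage lookup table (knot spacing 0.005 mV, linear
  interpolation) for the 31 voltage-dependent rate and current factors
  inside the time loops; `ionic_currents()` and `step_cell()` evaluate the
  exact formulas. Gates are advanced by plain Euler (no Rush–Larsen), to
  stay faithful to the explicit-Euler scheme of the study this package
  reproduces.

## Units and the $\kappa$ convention

Lengths are cm, time inputs ms, voltages mV, currents pA/pF, $\kappa$
cm²/s, wavenumbers rad/cm. One convention deserves emphasis because the
symbol is *not* scale-free when $\beta \ne 0$: the argument of the
logarithm must carry a unit choice, and the power law $|k|^\alpha$ changes
meaning with $\alpha$ unless a reference wavenumber is fixed. The package
uses:

* **log-periodic factor:** $\cos(\beta \ln k)$ with $k$ in rad/cm — this
  choice makes the $\beta \le 0.28$ operating range sit just inside the
  strand stability bound ($\beta_{\max} = 0.296$) and reproduces the
  relative conduction-velocity reduction observed at $\beta = 0.28$;
* **power law:** the tissue configuration applies
  $\kappa_{\mathrm{eff}} = \kappa \cdot k_{\mathrm{ref}}^{-\alpha}$ with
  $k_{\mathrm{ref}} = 0.5$ rad/cm. This reference is pinned once by the
  calibration that defines the $\kappa$ tables: $\kappa = 0.40$ cm²/s at
  $\gamma = 2 + j0$ must propagate a non-remodeled plane wave at 63 cm/s.
  With the reference in place, the tabulated $\kappa$ values for
  $\alpha < 2$ (0.59 … 10.28 cm²/s) reproduce their conduction velocities
  to a few percent without further adjustment. Setting
  `k_power_ref = 1` exposes the raw spectral convention.

`spectral_symbol()`, `apply_H()` and `diffusion_propagator()` always use
the pure symbol; the reference enters only where a tabulated $\kappa$ is
interpreted (`strand_config()`/`sheet_config()`).

## Study conditions and problem sizes

The package defaults encode the study conditions it reproduces:

* single-cell characterization: 60 s of pacing, 2-ms pulses at twice the
  diastolic threshold (the cell-level threshold is found by bisection to
  1%); the single-cell comparison between baseline and CAF uses a 1-Hz
  train, whose last beat reproduces the published APD90 and resting
  potential contrast (≈293 vs ≈96 ms; −81.0 vs −84.9 mV in this
  implementation);
* tissue initial conditions: every node starts from the final state of a
  CAF cell paced 60 s at BCL 400 ms;
* strand: $L = 2$ cm at $N = 128$ ($\Delta x = 156.25$ µm), stimulated at
  the left 5 nodes, probes at $L/3$ and $2L/3$; restitution uses 10 S1
  beats at BCL 1000 ms plus one S2 per coupling interval (the S1 train is
  simulated once and snapshotted — the scheme is deterministic, so
  continuing from the snapshot equals rerunning the train);
* sheet: $4.115$ cm at $N = 128$ ($\Delta x = 321.5$ µm; the nominal 4-cm
  domain is enlarged to the nearest power-of-two grid), S1–S2 cross-field
  induction with S1 at the left edge and S2 over the lower-left quadrant.

The test-suite rotor episodes run on a half-resolution $64 \times 64$
sheet (same 4.115-cm extent) — rotors there are qualitatively equivalent
but cheaper by 4×; the full-resolution protocol is available through the
same functions and the `cardiofrac` command-line driver.

## Phase analysis choices

The rotor tip is the phase singularity of the Hilbert phase: each node's
voltage series is de-meaned, the analytic signal computed by the standard
FFT construction, and the phase taken as `atan2(Im(analytic), V - mean)`.
The de-meaning makes the phase independent of DC offsets; the overall phase
convention is irrelevant to the winding number. Singularities are detected
by summing wrapped phase differences around every 2×2 plaquette (threshold
$|{\sum}| \ge \pi(2 - \varepsilon)$, $\varepsilon = 0.1$); tips are linked
into filaments by nearest-neighbor association with a 0.3 cm/frame jump
limit. The rotor core is reported as the temporal-mean tip position, the
spatial stability as the maximal pairwise tip distance $D$ (time ignored),
and a "sustained rotor" requires a persistent singularity whose filament
accumulates at least two full rotations of unwrapped phase at the node
nearest the core — plane waves sweeping a point also advance its phase, so
rotation counting alone would misclassify paced beats.

## What the synthetic fixtures do and do not show

`make_fixture()` provides closed-form inputs: a sine eigenmode for the
operator, a constant-speed logistic wavefront for conduction-velocity
plumbing, and a rigidly rotating spiral with a known tip, angular velocity
and chirality for the phase pipeline. These validate the *analysis
machinery* exactly, but they are noiseless, perfectly periodic and
rigidly rotating — unlike simulated (let alone real) fibrillatory
dynamics, where tips meander, annihilate in pairs and drift. Passing
fixture tests therefore certifies the detectors, not the physiology; the
physiological surface is exercised by the paced-cell, strand and sheet
simulations themselves.

## Known limitations

* The strand APD90 level in this implementation sits ~20–26% below the
  values reported for the mid-strand cell in the study it reproduces,
  while the single-cell APD90, the resting potentials, the $\beta = 0$
  conduction-velocity table and the APD *differences* across $\gamma$ all
  match within a few percent. The discrepancy is documented rather than
  calibrated away; candidate explanations (agonist-free strand runs,
  alternative initial states, measurement-beat choices) were tested and do
  not close the gap.
* At $\gamma = 1.1 + j0.28$ propagation fails (as reported); in this
  implementation the failure boundary already includes
  $\gamma = 1.2 + j0.28$ on the 321.5-µm geometry, where the reference
  study still observes slow conduction.
* 2-D only; no anisotropy, fiber architecture, 3-D scroll waves or
  spatially varying $\gamma$.
* Explicit Euler at $\Delta t = 0.01$ ms carries the accuracy burden of
  the reaction step; halving $\Delta t$ moves conduction velocities by
  well under 1%.
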