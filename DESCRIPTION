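Package: cardiofrac
Title: Complex Fractional-Order Diffusion Modeling of Atrial Action-Potential Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates atrial action-potential propagation on strands and 2-D
    sheets under a complex fractional-order diffusion operator: a
    complex-conjugate pair of spectral fractional Laplacians, realized as a
    real Fourier multiplier, coupled to the Courtemanche-Ramirez-Nattel human
    atrial ionic model with chronic-atrial-fibrillation electrical remodeling
    and an acetylcholine-dependent potassium current. Provides S1-S2
    cross-field rotor induction, restitution and vulnerable-window protocols,
    electrophysiological biomarkers (APD90, conduction velocity, APD
    dispersion, peak-current profiles), and Hilbert-phase rotor-tip analysis
    with phase-singularity tracking and the maximal tip-displacement metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
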