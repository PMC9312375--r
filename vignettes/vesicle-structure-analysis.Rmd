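---
title: "Methods: scattering and densitometric analysis of unilamellar vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scattering and densitometric analysis of unilamellar vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclefit)
```

This vignette records the models behind `vesiclefit`, the conventions and
tunable parameters that matter, the numerical choices, and what the
synthetic-data validation does and does not demonstrate.

## The measurement problem

Extruded unilamellar phospholipid vesicles (ULVs) of POPC, dispersed at
around 1 wt% lipid, are probed three ways: small-angle neutron scattering
(hydrogenated lipid in D₂O for maximal contrast, q ≈ 0.005–0.5 Å⁻¹),
small-angle X-ray scattering (q up to 1.3 Å⁻¹), and vibrating-tube
densitometry over 20–30 °C. SANS constrains the vesicle size and the overall
bilayer thickness; SAXS resolves the inner electron-density structure of the
bilayer through the head-group peaks; densitometry gives the molecular
volume. Together they yield the quantities that decide whether an additive
restructures the membrane: bilayer thickness `d_L`, head-to-head distance
`d_HH`, volume per lipid `V_L`, area per lipid `A_L = 2 V_L / d_L`, and the
mean interlipid distance `sqrt(A_L)`.

## SANS model: polydisperse single-shell vesicle

A vesicle is a spherical shell of uniform scattering length density between
the core radius `R` and `R + d_L`. Conventions:

* `R` is the **inner (aqueous core) radius**; the outer radius is
  `R + d_L`. All reported radii follow this convention.
* Polydispersity is a Schulz (gamma-type) distribution of `R` with
  `p = sigma_R / R` and shape `z = 1/p^2 - 1`; the shell thickness is
  monodisperse. Averaging is number-weighted, and the intensity is
  normalised by the equally weighted mean shell volume.
* Defaults for synthetic neutron data: solvent SLD `6.34e-6` 1/A^2 (D₂O),
  shell SLD `-0.3e-6` 1/A^2 (average hydrogenated lipid), i.e. the
  high-contrast condition the experiment is designed for. The shell SLD is a
  free parameter in principle (bounds `[-1, 3]e-6`), but the default fits
  leave it fixed: with a single homogeneous shell it is fully degenerate
  with the intensity scale.
* No instrument resolution smearing is applied; the q-grids are treated as
  exact. A smearing kernel would convolve additional width into the pit
  region and is out of scope here.

### Closed-form Schulz average

The shell amplitude difference can be written, with `u = qR`, `w = q d_L`
and `g(x) = sin x - x cos x`, as
`g(u + w) - g(u) = (A + B u) sin u + (C + D u) cos u` where `A, B, C, D`
depend only on `w`. Its mean square over the Schulz distribution therefore
needs only the raw moments `E[R^m]` and the complex moments
`E[R^m e^{2iqR}]`, `m = 0, 1, 2`, all closed-form for a gamma distribution.
This is the default evaluation path (`method = "exact"`).

The reason for preferring it over quadrature is quantitative, not
aesthetic: at `q = 0.5` 1/A the integrand oscillates in `R` with period
`pi/q ≈ 6` A while the distribution support spans ~1000 A. A generic
fixed-grid rule with fewer than several hundred nodes aliases these
oscillations — near the resonance `2 q h ≈ 2 pi` the quadrature error is of
the same order as the intensity itself, while the true oscillatory
contribution is analytically damped to nothing by the characteristic
function. A composite Gauss–Legendre path (`method = "quadrature"`,
`n_quad` nodes) is retained purely as an independent cross-check; it signals
non-convergence whenever doubling `n_quad` moves any point by more than
0.1%, which a 64-node rule does on the full q range (the tests assert
exactly this, and that a 512-node rule agrees with the closed form).

### Size observables

The low-q "pit" of the monodisperse curve sits at `2 pi / q` close to the
outer vesicle diameter (~680 A for the neat system; tested within 15%). At
the study's polydispersity `p = 0.3` the pit is fully washed out —
consistent with it being only weakly pronounced in measured curves — which
is why the size information in real fits is low-resolution. The fitted
distribution is summarised by its FWHM (`schulz_fwhm()`), located by exact
mode + root bracketing.

## SAXS model: symmetric 3-Gaussian bilayer

The relative (solvent-subtracted) electron density along the bilayer normal
is two positive head-group Gaussians at `±z_H` and one negative tail
Gaussian at the midplane. Its cosine transform is analytic, and
`d_HH = 2 z_H` is the head-to-head (phosphorus–phosphorus) distance.
Conventions and defaults:

* Widths are fixed at `sigma_head = 3.6` A and `sigma_tail = 5.8` A (the
  accepted fluid-phase POPC values at 25 °C); freeing them invites fit
  divergence without adding information at this resolution.
* Amplitudes are *relative* electron densities; `rho_head > 0 > rho_tail`
  is enforced. There is no sign degeneracy at fixed positive `rho_head`,
  but `scale` and the amplitudes are jointly degenerate (the intensity
  depends on `scale * rho^2`); fits that free both recover `z_H` exactly
  while reporting the amplitude covariance as undetermined. Fixing `scale`
  resolves this when amplitude values themselves are wanted.
* The default intensity uses the thin-sheet separated-form-factor
  `1/q^2`, valid for `q >= 3/R_ves`; the evaluator refuses q below that.
  The alternative spherical-shell factor, a Schulz-smeared thin-shell
  sphere average normalised to `1/q^2` at large smearing, exists for
  validation; the two agree to <1% over `q in [0.05, 1.3]` 1/A at
  `R_ves = 300` A, `sigma_R = 90` A (tested). Low-q SAXS carries little
  size information at this resolution, so fits default to the window
  `[0.05, 1.3]` 1/A with `R_ves`, `sigma_R` fixed.

## Fitting and uncertainties

`sas_fit()` minimises `chi^2 = sum((I_model - I)/sigma)^2` with
Levenberg–Marquardt under box constraints, initial values taken from the
supplied model object. Uncertainties follow the small-angle convention: the
covariance of the weighted-residual Jacobian, scaled by the reduced
chi-square before the square root, `stderr_j = sqrt(cov_jj * chi2_red)`.
This is the dimensionally consistent reading of "covariance matrix
multiplied by the root of the normalized chi-square", and it makes the
quoted errors invariant under a global rescaling of the data sigmas (the
tests assert the exact cancellation). Singular covariance is reported as
"undetermined", never as silent zeros. `profile_uncertainty()` validates
the covariance errors by chi-square profiling at `chi2_min + chi2_red`
(the `+1` criterion expressed on the scaled-error scale, so a quadratic
surface reproduces `stderr` exactly); parameters at a bound yield a flagged
one-sided interval.

Default q-windows are the instrument ranges: `[0.005, 0.5]` 1/A (SANS) and
`[0.05, 1.3]` 1/A (SAXS). Fits are deterministic; an optional restart
mechanism in the CLI perturbs initial values by ±20% under a seed and keeps
the best converged fit.

## Densitometry

The apparent specific volume of the lipid,
`v = (1/rho_disp - (1 - w_L)/rho_buf) / w_L`, converts to
`V_L = v M_L / N_A` with `M_L(POPC) = 760.08` g/mol. The buffer density is
subtracted as measured — deliberately no correction for ion depletion by
adsorption, matching experimental practice; this is a known caveat at the
highest salt concentrations. The systematic error defaults to 3 A^3, the
midpoint of the 2–4 A^3 sample-preparation error budget, and drives the
"no change" band in `volume_vs_concentration()`: a concentration series is
called flat when every `V_L` lies within ±sys_err of the 0 mM value.
Thermal expansivity is the OLS slope of `ln V_L` vs `T` (invariant under
°C↔K shifts). Change flagging in `structural_summary()` uses the combined
1-sigma propagated errors, `|delta| > sqrt(err_new^2 + err_ref^2)`.

## Leaflet number ratio

For the outer/inner leaflet lipid-count ratio, the package places the
bilayer midplane at `R + d_L/2` and each leaflet's mid-surface at
`±d_L/4` from it, giving
`N_out/N_in = ((R + 3 d_L/4)/(R + d_L/4))^2` under equal area per lipid in
both leaflets. This convention is chosen because it reproduces the accepted
value 1.13 for a 300 A vesicle with a 40.5 A bilayer; at `R = 200` A it
gives 1.20, whereas a commonly quoted literature figure is 1.22 — the
difference reflects differing leaflet-surface conventions in the
literature, and ours is documented rather than asserted as unique.

## Synthetic data: what it does and does not show

The generators produce every input the pipeline consumes, with known ground
truth: SANS and SAXS curves (log-spaced grids over the instrument ranges)
and density series whose inversion is exact by construction. Noise is
multiplicative Gaussian by default (2% SANS, 3% SAXS — a simple stand-in
for counting statistics; a Poisson option exists), with `sigma = noise * I`
reported, and all randomness flows through explicit seeds (a seed is
mandatory for any noisy output). For noiseless curves the sigma column is a
nominal counting-statistics-like weight `0.01 sqrt(I * I_max)`: purely
relative weights would let the machine-precision high-q thickness fringes
dominate chi-square and carve phase-slip local minima that no single-start
optimizer should be asked to escape, whereas the square-root profile mirrors
how real count-limited uncertainties grow toward weak high-q points.

The default scenario (`popc_truth()`) encodes the neat-POPC state and the
qualitative titration trends: radius shrinking 300→200 A over 0–50 mM,
thickness and volume flat to 30 mM with a 0.5 A thickness dip and a small
volume shift at 50 mM.

What passing recovery tests demonstrate: the estimators are unbiased and
exact on data drawn from their own forward models, the chi-square
calibration is correct (mean reduced chi-square in [0.8, 1.2] over 50 noisy
replicates), and the error propagation is internally consistent. What they
do not demonstrate: robustness to model misspecification (instrument
smearing, residual multilamellarity, structured backgrounds, inter-vesicle
interference), which real data contain and synthetic data by construction
do not.

## Numerical choices

* Sphere kernel: series `1 - x^2/10 + x^4/280` below `x = 0.01` (switch
  continuous to ~1e-16); closed form above.
* Schulz pdf in log space (stable to `p = 1e-4`, i.e. `z = 1e8`); complex
  moments via `exp(-(k+m) log(1 - it/b))`.
* Covariance inverted on the correlation scale (reciprocal condition
  threshold 1e-10) so that mixed parameter units do not masquerade as
  singularity.
* Jacobians: central differences with relative step 1e-6, clipped to the
  box.
* Quadrature cross-check: composite Gauss–Legendre, 16-node panels via
  Golub–Welsch.
* Problem sizes used in the shipped tests: 120-point SANS grids, 180-point
  SAXS grids, 50-replicate chi-square calibration, 200-replicate
  expansivity bias check — sizes at which every estimator's behaviour is
  already asymptotic.

## Known limitations

* Single homogeneous shell for SANS: no head/tail contrast splitting, so
  `d_L` is a Luzzati-style overall thickness; shell SLD and scale are
  degenerate.
* No resolution smearing; fitted polydispersity absorbs any instrumental
  width.
* The flat-sheet SAXS branch is invalid below `q = 3/R_ves` (enforced).
* Densitometry assumes dilute, non-interacting dispersions and no ion
  depletion; `A_L` from `2 V_L/d_L` is systematically low relative to
  bilayer-structure literature values (~64 A^2 for POPC) because `d_L`
  from a single-shell SANS fit is an overall thickness, not a hydrophobic
  one.
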