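---
title: "Estimating turgor pressure from protoplast osmometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating turgor pressure from protoplast osmometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmometry)
```

## The measurement principle

A walled cell such as a yeast maintains an internal hydrostatic (turgor)
pressure P because its internal osmotic potential Π_C exceeds that of the
medium, Π_buffer; at mechanical equilibrium P = Π_C − Π_buffer. A
protoplast — the same cell with its wall enzymatically removed — cannot
sustain any pressure difference, so it swells or shrinks until its internal
osmotic potential matches the medium exactly. It is, to first order, an
*ideal osmometer*: its volume is linear in the inverse of the total external
osmolarity (the Boyle Van't Hoff relation),

$$ V = \frac{m_0}{C_\mathrm{total}} + b_0, $$

with slope $m_0$ (the apparent amount of osmotically active content, µm³
mol/L) and intercept $b_0$ (the non-osmotic volume: macromolecules and
organelles that do not exchange water).

If one finds the external sorbitol concentration $c_\mathrm{iso}$ at which a
protoplast population matches the intact-cell population — in volume, in
cytoplasmic concentration, or in cytoplasmic rheology — then the intact
cell's turgor follows from the Van't Hoff relation

$$ P = c_\mathrm{iso} \, R \, T, $$

with R = 8.314 J/(mol K) and T = 303.15 K (30 °C, the growth temperature)
by default. Only the *added* sorbitol enters: the growth-medium osmolarity
is common to protoplasts and intact cells and cancels in
P = Π_C − Π_buffer. A concentration of 0.40 mol/L corresponds to about
1.0 MPa at 30 °C.

The package implements the three matching methods as classed model fits
(`bvh_fit`, `intensity_fit`, `phillies_fit`) with the usual `coef`,
`predict`, `summary`, `plot` and `residuals` methods, and a `run_pipeline()`
driver that combines them into a per-strain report.

## Method 1: cell volume

`fit_bvh()` performs ordinary least squares of the population summary volume
against $1/C_\mathrm{total}$. Choices that matter:

* **Central statistic.** The median of each population's volume
  distribution is the default (asynchronous populations have long right
  tails); the mean is available via `statistic = "mean"`. The intact-cell
  target is the average of per-replicate medians, and its between-replicate
  SD enters the error budget.
* **One point per condition and replicate**, unweighted. Replicates are kept
  as separate points rather than pooled so that replicate-level variation
  is visible to the regression; `pooled = TRUE` collapses them.
* **Abscissa** is total osmolarity, added sorbitol plus the growth-medium
  baseline; the baseline is a required input since media osmolarity is
  strain- and recipe-specific.

`invert_bvh()` solves $m_0/(V_\mathrm{intact} - b_0)$ for the isotonic total
osmolarity and subtracts the baseline. Degenerate inputs are errors, not
warnings: a target volume at or below $b_0$ has no positive solution, and a
negative isotonic sorbitol concentration means the intact cells appear
hypotonic to their own medium, which indicates a calibration problem.

## Method 2: cytoplasmic fluorophore intensity

Because the amount of a constitutively expressed cytoplasmic fluorophore is
fixed on osmotic-shock timescales, its concentration — and hence the
background-corrected fluorescence — is proportional to 1/volume. Intensities
are calibrated per slide against an intact-cell population imaged under
identical settings, so `normalized = 1` means "same cytoplasmic
concentration as intact cells"; this cancels slide-to-slide and day-to-day
gain exactly (a property the test suite checks as an invariance).

The response of normalized intensity to sorbitol is *not* globally linear:
it is $V_\mathrm{intact}/(m_0/(C_\mathrm{total}) + b_0)$, concave in C
because of the non-osmotic volume. A straight line is an excellent local
model near the intact level, which is why the fit is restricted to a window
of conditions close to normalized intensity 1. The default window takes the
3 conditions whose mean normalized intensity is nearest the target
(`intensity_window()`, `k = 3`). With a wider window the linearization bias
grows with the curvature times the window variance; with only the two
bracketing conditions the fit degenerates to interpolation and the variance
roughly doubles. Three conditions keeps the linearization bias below the
sampling error at the default study design. `window = "all"` reproduces the
unrestricted regression.

`invert_intensity()` solves the fitted line at target 1.0; its error
combines the fit covariance with the between-replicate variance of the
intact normalized mean. Self-calibration makes the latter exactly zero
when the calibration population is the target population, in which case the
within-slide standard error of the intact mean is used instead.

## Method 3: cytGEMs nanorheology

40-nm genetically encoded multimeric nanoparticles (cytGEMs) are passive
tracers of cytoplasmic crowding. Each 2D track (nominally 500 frames at
100 fps) yields a time-averaged mean squared displacement; the effective
diffusion coefficient is the through-origin slope of the first 10 MSD lags
divided by 4 (`compute_msd()`, `fit_deff()`). The ensemble estimate fits the
ensemble-mean MSD; its SEM is taken across per-track fits.

Across sorbitol conditions, D_eff follows the Phillies law for
self-diffusion in crowded polymer solutions,

$$ D_\mathrm{eff} = D_0 \, e^{-\beta (C + C_0)}, $$

with $D_0$ = 13.56 µm²/s the Stokes–Einstein diffusion of a 40-nm sphere in
water — treated as a fixed, opaque constant — and $C_0$ the medium
osmolarity, fixed rather than fitted. `fit_phillies()` estimates β by
regressing $\log(D_\mathrm{eff}/D_0)$ on $-(C + C_0)$ through the origin;
`fit_space = "linear"` provides a nonlinear least-squares alternative that
agrees with the log-space fit on clean data (checked to 1e-6 in the tests).
`invert_phillies()` matches the intact-cell D_eff on the fitted curve.

Numerical notes:

* The MSD fit is through the origin, following the 2D Brownian law. Static
  localization error adds a constant $4\sigma_\mathrm{loc}^2$ offset to
  every MSD lag, which a through-origin fit absorbs as a small upward bias
  in D_eff ($\sigma_\mathrm{loc}^2 \sum\tau_k / \sum\tau_k^2 / 4$ in the
  fitted window). Because the bias enters both the protoplast calibration
  curve and the intact-cell target, it largely cancels in the matching; the
  synthetic recovery tests quantify the residual (a few percent at
  $\sigma_\mathrm{loc}$ = 0.03 µm).
* Tracks shorter than `min_frames` (default 11, one more than the fitted
  lags) are excluded with a logged count.
* A measured $D_\mathrm{eff} \ge D_0$ is unphysical for the model and is an
  error, not a warning.

## Error combination and cross-method averaging

Each inversion propagates two variance sources to concentration units by
the first-order delta method — the calibration-fit parameter covariance and
the intact-cell target statistic's variance — and adds them in quadrature
(`combine_errors_delta()`). A bootstrap alternative (resampling cells within
condition × replicate) is available for the volume method behind
`bootstrap = TRUE`; the test suite checks that the two agree within 20% on a
seeded dataset.

The study-level value is the arithmetic mean of the per-method pressures
with the sample SD (n − 1) across methods as its error
(`combine_methods()`). Full precision is kept internally; pressures are
displayed at 2 significant figures and concentrations at 2 decimals.
Because displayed values are rounded last, converting *rounded* per-method
concentrations does not exactly reproduce per-method pressures computed
from unrounded intermediates; the discrepancy is bounded by about 0.02 MPa
and is documented rather than asserted.

## Cell-wall mechanics

For a rod-shaped cell with a homogeneous, isotropic thin wall, the force
balance $\Delta P \cdot R / (Y h) = \varepsilon$ links turgor to the lateral
wall's Young's modulus; `young_modulus()` evaluates it with inputs in MPa,
µm and nm, and `wall_tension()` computes $T = \Delta P \cdot R$ (MPa·µm is
exactly N/m). Absolute moduli need user-supplied geometry; cross-species
comparisons need only ratios (`scale_young()`), and the identities "half
the turgor at twice the radius and twice the thickness gives half the
modulus and equal tension" hold exactly.

## The synthetic-data generators

`study_scenario()` fixes a ground truth and design; three generators emit
the exact CSV schemas the methods consume. They emulate:

* lognormal cell-to-cell volume spread (CV 25% by default, resembling
  measured volume distributions) around medians that obey the osmometer law
  exactly, with $m_0$ chosen so the isotonic sorbitol concentration equals
  the scenario truth;
* per-cell intensities proportional to 1/volume with slide-level
  multiplicative gain (default gains 0.8 and 1.2) and additive background,
  with an intact calibration population on every slide;
* 2D Gaussian random walks with per-step variance $2 D \Delta t$ per axis,
  D following the Phillies law per condition, plus independent 0.03 µm
  localization noise; intact-cell tracks diffuse at the D implied by the
  scenario truth.

Default design: 6 sorbitol conditions (0.10–0.85 mol/L) spanning the
truth, 2 replicates, 100 protoplast cells per condition and replicate,
1000 tracks of 500 frames per condition, and a medium baseline of
0.20 mol/L. The intact reference population is sampled more deeply (500
cells per replicate) because every method inverts at it, so its sampling
error enters all three estimates; deep sampling of the calibration standard
mirrors practice. The default Phillies β = 5.6 L/mol places the intact-cell
D_eff at 0.40 µm²/s, matching measured wild-type fission-yeast cytGEMs
mobility. These sizes keep the full three-method recovery study (20 seeds
per method) to a few minutes on one CPU.

In the zero-noise limit every generated observable satisfies its governing
law exactly (linearity in 1/C, inverse-volume intensity, 4Dτ MSD,
exponential D(C)), and each pipeline returns the scenario truth; the test
suite asserts both, plus seeded parameter recovery at the default noise
levels.

What the generators deliberately do **not** emulate: segmentation errors in
3D volumes, vacuole contamination of intensity ROIs, photobleaching,
osmotic-shock transients and regulatory volume responses, tracking/linking
mistakes, or anomalous (sub-diffusive) tracer motion. Passing recovery
tests therefore demonstrates the estimators' correctness and calibration
under the stated statistical model, not robustness to these experimental
artifacts.

## Known limitations

* Sorbitol is treated as an ideal osmolyte; no activity coefficients.
* The intensity response is linearized locally; estimates far outside the
  fitted window carry a warning note rather than an error.
* The thin-shell mechanics assume an isotropic, homogeneous wall; tip
  growth and anisotropy are out of scope.
* Population-level matching yields population-level turgor; the methods do
  not resolve cell-to-cell variability.
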