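---
title: "Q-space imaging of skeletal muscle: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Q-space imaging of skeletal muscle: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsimuscle)
```

## The measurement model

Diffusion MRI with a pulsed-gradient spin-echo (PGSE) sequence encodes water
displacement through a pair of gradients of duration $\delta$ separated by
$\Delta$. The wavevector magnitude $q = \gamma\delta G / 2\pi$ and the
diffusion weighting are tied by the Stejskal–Tanner relation

$$b = (2\pi q)^2\,(\Delta - \delta/3),$$

with effective diffusion time $t_d = \Delta - \delta/3$. `gradient_scheme()`
enforces this relation on every shell of a protocol (1 % relative
tolerance), so a b-table and a q-table that disagree physically are rejected
at load time with the offending shell named. The acquisition emulated
throughout the package uses ten shells ($b$ = 0–4000 s/mm², $q$ =
0–528.3 cm⁻¹) at $\Delta/\delta$ = 45.6/27.9 ms ($t_d$ = 36.3 ms) and six
encoding directions — the dual-gradient set $(\pm 1, \pm 1, 0)$-type
normalized vectors, whose design matrix for a symmetric tensor has full
rank 6.

Two analyses run on the same data:

* **DTI radial diffusivity.** Per direction, a two-point monoexponential
  ADC from the $b = \{0, 800\}$ s/mm² pair only,
  $\mathrm{ADC} = -\ln(S_b/S_0)/b$, then a least-squares symmetric tensor
  $g_i^\top D g_i = \mathrm{ADC}_i$ and
  $\mathrm{RD} = (\lambda_2 + \lambda_3)/2$. The higher shells are
  deliberately ignored here; that is what defines RD in this protocol.
  With exactly six independent directions the least-squares solve is a
  square linear system and the recovery of a noise-free Gaussian tensor is
  exact to machine precision (the test suite checks $10^{-6}$ relative on
  RD and $10^{-9}$ on rotation equivariance of the spectrum).

* **Q-space imaging (QSI).** Per direction, the normalized attenuation
  $E(q)$ over all ten shells is Fourier-transformed into the 1-D
  displacement probability density (the propagator); its full width at
  half maximum (FWHM, µm) is the restriction-scale readout. Six directional
  FWHM values are combined into a tensor, and the **radial FWHM** —
  $(\lambda_2 + \lambda_3)/2$ of the eigen-magnitudes — summarizes
  displacement width perpendicular to the fibre axis, the quantity that
  tracks muscle-fibre diameter.

## From six directional widths to three eigenvalues

How six directional FWHM measurements become a tensor is genuinely open:
for a Gaussian propagator, $\mathrm{FWHM}_g = \sqrt{16\ln 2\, t_d\,
g^\top D g}$, so the *squared* FWHM — not the FWHM itself — is exactly a
quadratic form in the direction. `fit_fwhm_tensor()` therefore fits
$\mathrm{FWHM}_i^2 = g_i^\top F g_i$, eigen-decomposes $F$ and reports
$\lambda_k = \sqrt{\max(e_k, 0)}$. This makes the construction
self-consistent in the Gaussian limit: for a cylindrically symmetric
tensor the pipeline's radial FWHM converges to
$\sqrt{16\ln 2\, t_d\, \mathrm{RD}}$, which the tests verify within 3 %
(the residual is transform discretization, see below). An alternative mode
(`tensor_mode = "unsquared"`) fits the FWHM values directly and is provided
for sensitivity analysis only; the two modes agree exactly on isotropic
voxels and diverge with anisotropy.

## PDF reconstruction: numerical choices

`reconstruct_pdf()` implements the transform as:

1. normalize so $E(0) = 1$ (per voxel, by the mean of the b = 0
   replicates; a non-maximal $E(0)$ triggers a warning and
   renormalization);
2. resample onto a uniform q grid by monotone (Fritsch–Carlson) Hermite
   cubic interpolation — the printed q samples are slightly non-uniform
   and the discrete transform needs uniform spacing; linear interpolation
   is available via `interp = "linear"` and agrees within ~5 %;
3. extend evenly to negative q (the propagator of a real, even signal is
   real and even);
4. zero-fill to `grid_size` (default 4096) and FFT.

With `n_resample = 21` uniform samples over $[0, q_{max}]$
($\Delta q = 2641.5\ \mathrm{m}^{-1}$), the displacement grid spacing is
$1/(4096\,\Delta q) \approx 0.092$ µm, so the FWHM readout — linear
interpolation between the two half-maximum bracketing samples, scanning
outward from the peak — is sub-resolution without any ringing-sensitive
peak fitting. Truncation ringing can produce small negative density lobes;
they are left in the array (the unit-integral invariant is evaluated before
any clipping — the discrete integral equals $E(0)$ identically) and the
outward half-max scan stops at the first crossing, so the lobes never
influence the width.

Two resolution effects matter when interpreting absolute widths:

* the q-space window is finite, so a point-like propagator reads out at the
  transform-limited width $\approx 1/((2M{-}1)\Delta q) \approx 9$ µm, not
  zero;
* when the signal has not decayed at $q_{max}$ (directional ADC below
  roughly $0.7\times10^{-3}$ mm²/s under this protocol), the hard
  truncation broadens the measured FWHM by more than the nominal 3 %
  discretization tolerance. Real muscle (RD $\sim 1.4\times10^{-3}$ mm²/s)
  and all quantitative tests sit in the adequately-decayed regime; the
  weak-attenuation regime is exercised only qualitatively.

## The synthetic phantom

Human scans for this protocol are not publicly deposited, so validation
runs on a phantom with known ground truth. Two compartment models:

* **Gaussian tensor** — $E = \exp(-b\,g^\top D g)$, for closed-form
  recovery targets;
* **restricted cylinder** — free axial diffusion times a perpendicular
  factor from the Gaussian phase distribution (GPD) approximation, a
  Bessel-root eigenmode series truncated at $10^{-12}$ relative. The
  gradient duration here ($\delta = 27.9$ ms) is far from the narrow-pulse
  regime, which makes GPD the appropriate finite-pulse model; a
  narrow-pulse diffraction mode (`mode = "narrow_pulse"`) exists purely as
  an analytic cross-check. The GPD implementation is verified against an
  independently computed evaluation of the same series (SciPy Bessel
  roots, 50 modes) to $10^{-6}$.

Defaults chosen once and kept: intrinsic diffusivity
$2.0\times10^{-3}$ mm²/s (typical tissue water at body temperature), SNR 50
(the b0 signal divided by the Gaussian noise standard deviation; the study
itself reports no SNR, so this is an explicit assumption exposed in the
config), Rician noise applied independently per measurement (magnitude-MRI
convention). Because GPD attenuation is Gaussian in q at fixed timing, the
cylinder's radial FWHM is an increasing function of radius over the
physiological 10–100 µm range — the mechanism that lets the metric track
fibre diameter. The phantom does *not* model exchange/permeability, fat
compartments, distributions of fibre sizes within a voxel, partial volume
at muscle boundaries, or eddy-current/motion artifacts, so passing tests
demonstrate correctness of the computation, not robustness to everything
real data contains.

The Gaussian ground-truth target `true_radial_fwhm` is
$(\sqrt{16\ln2\,t_d\lambda_2} + \sqrt{16\ln2\,t_d\lambda_3})/2$ — exactly
what the QSI pipeline converges to in the noise-free Gaussian limit, which
is what makes it a parameter-recovery target rather than a tautology.

## ROI aggregation and cohort statistics

`roi_mean()` averages finite voxels under an integer label (invalid voxels
are excluded and counted); `replicate_average()` implements the
triplicate-then-left/right averaging scheme, whose estimator variance is
$\sigma^2/6$ for i.i.d. replicates; `cross_sectional_area()` converts a
label's voxel count on the reference slice to cm². Label masks drawn on a
finer anatomical grid are nearest-neighbour resampled onto the map grid —
labels must never be interpolated. The soleus is computed but flagged
`unreliable_crossed_fiber`: its crossed-fibre architecture breaks the
single-axis assumption behind both radial metrics.

Group comparisons use one-way fixed-effects ANOVA and Dunnett's
many-to-one procedure against the control group via `multcomp` (adjusted
p-values from the multivariate t-distribution; the quasi-Monte-Carlo
evaluation is wrapped in a fixed seed so repeated calls agree, accurate to
about $10^{-3}$). Correlation matrices use Spearman's rank correlation
with mid-ranks for ties and pairwise-complete observations (the common
convention when missingness is unspecified); p-values use the asymptotic
t approximation by default, with the exact small-sample null available via
`exact = TRUE`. Reported coefficients are rounded to two decimals in the
output tables.

`simulate_cohort()` generates the per-subject table the cohort statistics
consume: four groups of 12/10/11/10 with published group-level
body-composition means and SDs, and muscle metrics driven by each
subject's standardized SMI plus independent noise. It reproduces the
*structure* — positive radial-FWHM correlations with SMI/CSA/PA, and
powerlifting/teenager separating from control — without asserting any
particular coefficient, because the study's own per-subject values are not
deposited.

## Problem sizes and determinism

The validation suite uses a $16^3$ noise-free free-water volume for the
closed-form recovery check (about ten seconds), $10\times10$ voxel panels
per cylinder radius for the noise-robustness checks, 2000 null cohorts for
the ANOVA type-I calibration and 120 cohorts for the Dunnett power check —
sizes chosen to estimate each quantity comfortably within its assertion
tolerance. All randomness flows through explicit seeds: phantoms are
deterministic given `seed`, `run_pipeline()` writes an MD5 manifest whose
hashes are identical across reruns with the same seed (all volumes are
written as uncompressed `.nii` for byte-stable output), and the colour-map
renderer is a pure function of its inputs.

## Known limitations

* Absolute FWHM accuracy is bounded by the q-space window (see above);
  comparisons *between* tissues/radii are much more accurate than absolute
  widths near or below ~10 µm.
* The FWHM-tensor construction assumes a single dominant fibre axis per
  voxel; crossed-fibre muscle (soleus) violates it, hence the flag.
* Rician bias at SNR 50 shifts high-q measurements upward slightly,
  compressing large-radius contrast (visible as a small negative bias of
  the noisy radial FWHM against its noise-free value).
* The cohort generator is a structural stand-in, not a re-creation of the
  study sample; only rank-level patterns should be read from it.
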