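# qsimuscle

Noninvasive assessment of skeletal-muscle microstructure from q-space
diffusion MRI. Muscle fibres restrict water displacement across their
cross-section, so the width of the water-displacement probability density —
measured perpendicular to the fibre axis — tracks fibre diameter, a
quantity otherwise accessible only by biopsy. This package implements that
analysis for researchers in sports medicine and musculoskeletal imaging,
together with the phantom simulation and cohort statistics needed to
validate and apply it.

## What it computes

For a pulsed-gradient spin-echo acquisition with gradient separation Δ and
duration δ, the b- and q-values obey b = (2πq)²(Δ − δ/3); the emulated
protocol has 10 shells (b = 0–4000 s/mm², q = 0–528.3 cm⁻¹), Δ/δ =
45.6/27.9 ms and 6 encoding directions.

* **Displacement PDF per direction** — Fourier transform of the normalized
  attenuation E(q): resampled to a uniform q grid, evenly extended,
  zero-filled (default 4096) and FFT'd; the full width at half maximum
  (FWHM, µm) of the density is the restriction-scale readout
  (`reconstruct_pdf()`, `measure_fwhm()`).
* **Radial FWHM** — the squared directional FWHMs are fitted as a
  quadratic form FWHMᵢ² = gᵢᵀF gᵢ; with eigen-magnitudes
  λₖ = √(max(eₖ, 0)), the radial FWHM is (λ₂ + λ₃)/2 — displacement width
  perpendicular to the fibre axis (`fit_fwhm_tensor()`, `qsi_fit()`).
* **DTI radial diffusivity** — conventional two-point tensor fit on the
  b = {0, 800} s/mm² subset, RD = (λ₂ + λ₃)/2 (`dti_fit()`).
* **Phantom simulation** — Gaussian-tensor and restricted-cylinder
  (Gaussian phase distribution) compartments with Rician noise and known
  ground truth (`generate_phantom()`).
* **ROI aggregation** — label-mask means, triplicate + left/right
  replicate averaging, anatomical CSA (`roi_summary()`).
* **Cohort statistics** — one-way ANOVA, Dunnett comparisons against
  control, Spearman rank-correlation matrices with mid-rank ties
  (`anova_oneway()`, `dunnett_vs_control()`, `spearman_matrix()`).

All fitters take plain arrays or phantom objects and return tibbles, so
results chain directly into dplyr/ggplot2; `tidy()`, `glance()` and
`autoplot()` methods are provided.

## Worked example

Simulate muscle-like cylinders of 40 µm radius at SNR 50 and read out the
radial FWHM:

```r
library(qsimuscle)
sch <- muscle_protocol()
round(b_from_q(c(236.3, 528.3), 45.6, 27.9), 1)
#> [1]  800.2 3999.7        # the printed protocol's 800 and 4000 s/mm^2

ph  <- generate_phantom(phantom_spec(c(4, 4, 1),
         cylinder_compartment(radius = 40, diffusivity = 2e-3),
         sch, snr = 50, seed = 7))
fit <- qsi_fit(ph)
dplyr::select(fit, i, j, fwhm_1, flambda1, flambda2, radial_fwhm)
#>       i     j fwhm_1 flambda1 flambda2 radial_fwhm
#> 1     1     1   24.5     27.5     24.6        24.2
#> 2     2     1   23.8     27.5     24.3        24.0
#> ...
```

`flambda1` (≈27.5 µm, along the fibre axis, free diffusion) exceeds the
radial FWHM (≈24 µm), which is depressed by the 40 µm restriction; smaller
cylinders give proportionally smaller radial FWHM.

Cohort stage on a simulated per-subject table (four groups, 12/10/11/10):

```r
co <- simulate_cohort(seed = 1)
spearman_matrix(co[co$muscle == "ta", ], c("smi", "csa", "radial_fwhm"))
#>              smi  csa radial_fwhm
#> smi         1.00 0.88        0.83
#> csa         0.88 1.00        0.72
#> radial_fwhm 0.83 0.72        1.00

tidy(dunnett_vs_control(unique(co[, c("subject_id", "group", "smi")]), "smi"))
#> powerlifting - control   p = 2.9e-05
#> teenager - control       p = 5.8e-04   # both differ from control
```

Larger radial FWHM goes with larger muscle-mass index and cross-sectional
area, and the powerlifting and teenager groups separate from control on
SMI — the rank-level pattern the metric is designed to expose.

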