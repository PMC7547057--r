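---
title: "Methods: simulating CT-dose effects on PET attenuation correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating CT-dose effects on PET attenuation correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the design

A PET/CT reconstruction is only as quantitatively accurate as its
attenuation-correction (AC) map. When CT is acquired solely for AC, the
exposure should be minimised — but an inaccurate low-dose AC map biases
every standardised uptake value (SUV) downstream. The design implemented
here isolates the AC pathway completely: a single PET emission acquisition
of a torso phantom is reconstructed repeatedly, once per AC map, where the
AC maps come from 24 CT acquisitions (tube current 15/25/40/50 mAs, voltage
80/100/120 kVp, pitch 0.671/0.828) each reconstructed with filtered back
projection (FBP) and iterative reconstruction (IR). Because the emission
data, reconstruction algorithm and geometry are identical across all 48
reconstructions, every difference from the reference reconstruction
(50 mAs / 120 kVp / 0.828 / IR) is attributable to the AC map alone.

# The phantom

`phantom_spec()` describes a parametric torso: an elliptic-cylinder body
(soft tissue, SUV 1.0, 40 HU), two air-filled lungs (SUV 0, −800 HU), a
liver (SUV 2.5, 55 HU), a heart (SUV 4.0, 45 HU), a spine insert (no
activity, 700 HU), a 17-mm spherical "tumour" in the right lung (SUV 4.0)
and two soft-tissue cylinders lateral to the torso standing in for a
patient's arms (no activity). Compartments are rasterized by voxel-centre
membership in a fixed priority order, so the rasterized compartments are
exactly disjoint and compartment voxel values are exact (no noise in the
ground truth). The default grid is 128 × 128 × 40 PET voxels at 4 mm
isotropic with the CT grid supersampled ×2 in-plane (2 mm); the CT volume
is block-averaged back onto the PET grid before conversion to attenuation
coefficients. World coordinates put voxel centres at
`(index − (n+1)/2) · spacing`.

# The CT surrogate

The vendor CT reconstruction algorithms are not available and are not
simulated; `simulate_ct()` is a *behavioural* surrogate calibrated to
reproduce the statistical signatures that reach the PET chain. Its
parameters (`ct_sim_options()`) are:

* `noise_sd_1mGy` (18 HU): correlated quantum noise, standard deviation
  `noise_sd_1mGy / sqrt(CTDI)`, generated per slice by ramp-filtering
  (Hann-apodized) white Gaussian noise — the FBP noise texture. Each slice
  is normalised to the target SD exactly, so the 1/√dose law is exact
  before HU clipping; the noise-scaling test therefore measures it in soft
  tissue, away from the −1024 HU floor.
* `bh_amp_120` (12 HU): beam hardening. The squared water-equivalent path
  length is forward-projected and backprojected per slice, normalised, and
  subtracted with amplitude `bh_amp_120 · (120/kVp)²` inside the body —
  dark bands along the longest, densest chords (arms–spine corridor),
  stronger at low voltage. The artifact is deterministic per voltage and
  cached.
* IR surrogate, three components applied to the noisy image:
  1. edge-preserving (Perona–Malik) smoothing (`ir_smooth_iter` 4,
     `ir_kappa` 60 HU, `ir_lambda` 0.15) — the noise-variance reduction IR
     delivers;
  2. dose-dependent resolution loss: a Gaussian-blurred copy
     (`ir_blur_sigma_mm` 4) mixed in with weight
     `ir_blur_max · exp(−CTDI/ir_blur_tau)` (0.6 and 0.45 mGy) — at very
     low dose the regularisation is no longer edge-preserving, which
     displaces attenuation edges and concentrates PET errors at tissue
     interfaces;
  3. a negative CT-number bias
     `−ir_bias_hu · (HU+1000)/1000 · exp(−CTDI/ir_bias_tau)`
     (`ir_bias_hu` 80 HU, `ir_bias_tau` 0.45 mGy) — largest in dense
     voxels, vanishing as dose grows. This is the surrogate mechanism for
     the observed IR under-correction at low exposure.

The bias amplitude and dose constant were calibrated once so that, on the
simulated study, the lowest-exposure IR reconstructions underestimate the
liver mean by more than one QSD while every reconstruction above 1 mGy —
the study's convergence dose — lies within one QSD of the reference, and
FBP-based AC stays within one QSD at every exposure. FBP adds no
systematic term. Both reconstructions of one acquisition share the same
noise seed, as two reconstructions of one physical scan share raw data.

The CTDI model (`ctdi_model()`) is a calibration, not physics: a monotone
(Hyman-filtered) spline through the scanner-reported dose table per
voltage, anchored at (0 mAs, 0 mGy), interpolated linearly across voltage;
pitch does not enter (the reported table is pitch-independent at its
0.1-mGy precision). The source table reports the 25 mAs / 100 kVp dose
inconsistently as 0.9 and 1.0 mGy in different places; the calibration
adopts 1.0 mGy, the value used by the dose-reduction arithmetic, which
stays within the 0.1-mGy reporting precision of the other figure.

# PET simulation and reconstruction

`hu_to_mu()` applies the standard bilinear conversion to 511-keV linear
attenuation: `μ = 0.096·(1 + HU/1000)` cm⁻¹ below water, a shallower bone
segment (5 × 10⁻⁵ cm⁻¹ per HU) above, clipped at zero.

`simulate_pet()` forward-projects each slice with a pixel-driven
parallel-beam projector (72 angles over 180° by default, detector bins
equal to the voxel size, linear interpolation between bins), attenuates
each ray by `exp(−∫μ dl)` through the *true* μ map, scales the study so the
expected true counts average 2 × 10⁵ per slice (a clinically plausible
count density), and draws Poisson counts. `reconstruct_osem()` is a
standard attenuation-weighted OSEM (multiplicative updates, interleaved
angle subsets, nonnegativity preserved; default 3 iterations × 3 subsets,
matching smooth clinical reconstructions). Division guards make an
all-zero sinogram reconstruct to an all-zero image rather than erroring.

Counts are calibrated to SUV once per study: the reconstruction using the
true μ map is scaled so its whole-phantom mean matches the ground truth,
and that single factor is applied to all 48 reconstructions — the analogue
of a scanner's quantitative calibration.

All randomness derives from one master seed: `generate_study()` draws one
stage seed for the emission acquisition and one per CT acquisition (in grid
order) via `sample.int` under the master seed, and each stage restores the
caller's RNG state.

# The analyses

`roi_stats()` uses sample SD (n − 1) throughout — the conventional ROI
statistic; the tumour ROI's statistic of record is the maximum SUV (the
standard lesional metric, also less partial-volume sensitive), all others
the mean. ROI membership is voxel-centre-in-circle with ties at exactly
the radius counted inside. `suv_cov()` rejects non-positive means.

The voxel analysis defines QSD = sample SD of the reference liver ROI and
rejects a degenerate (non-positive) QSD. Exceedance uses the *absolute*
difference |RR − TR| with a *strict* inequality at the boundary. Two
conventions had to be fixed that the source design leaves open:

* **Percentage denominators.** The maximum/mean voxel difference is
  reported as `100·(RR − TR)/RR`, restricted to support voxels with
  RR > 0.1 SUV (`floor_suv`, configurable) — zero-activity lung and air
  voxels otherwise dominate the percentages with division blow-ups.
* **Support.** By default the t test and percentages run over the voxels
  inside the phantom (body support); in a simulator without scatter the
  surrounding air is exactly zero in both volumes and makes the test
  degenerate. A whole-volume mode (`support = "all"` in `run_config()`,
  `support = NULL` elsewhere) is provided, since the physical study used
  the entire volume.

No multiple-testing correction is applied across the 47 TR-vs-RR tests,
mirroring the original analysis. The reference compared with itself
returns the defined degenerate result (`NA`) rather than an error.

`spatial_localization_score()` reports, for each labelled region, the
exceedance rate and its enrichment over the global rate.
`localization_regions()` builds the standard set: high-activity
compartments (heart, tumour, liver — activity above background),
attenuation-interface shells (both sides of boundaries with > 100 HU
contrast, thickness configurable), the arm–spine beam-hardening corridor,
remaining body, and background air. Masks may overlap; rates are computed
independently.

# Calibration targets and what the tests show

On the reduced-resolution study (64 × 64 × 16 at 8 × 8 × 10 mm, five
seeds), the simulator reproduces the design's qualitative findings, and the
test suite asserts them: exceedance nonincreasing in dose at fixed
algorithm *and voltage* (at matched CTDI the 80-kVp acquisitions stay
worse — low-voltage insufficiency is itself one of the findings, and makes
mixed-voltage monotonicity false); IR worse than FBP at the lowest dose in
both exceedance and liver bias, with the IR liver bias exceeding one QSD;
all reconstructions above 1 mGy within one QSD of the reference; and
exceeding voxels enriched in high-activity regions and attenuation
interfaces for low-dose IR. The ΔCOV spread across protocols shrinks as
dose rises.

Parameter recovery is verified separately: with the true μ map, high
counts (5 × 10⁶ per slice) and a long run (60 iterations × 12 subsets, 96
angles on a 96 × 96 × 16 grid), all four compartment means — including the
slow-converging small tumour — recover within 5% over five seeds. The
default 3 × 3 setting is deliberately under-converged, like the smooth
clinical protocols it mimics; convergence checks therefore use their own
settings. Problem sizes throughout the tests (coarse grids, 24–96 angles)
were chosen as the smallest at which each property is stable.

# Known limitations

* The surrogates reproduce signature *directions and orderings*, not the
  physical study's numeric values; the printed exceedance percentages of
  the original (e.g. ~6% at the lowest-dose IR) depend on scanner, counts
  and QSD and are matched only in order of magnitude.
* Because all reconstructions share one emission realisation, ΔCOV
  magnitudes are smaller than physical ones (no independent emission noise
  between matched reconstructions) — the variability-vs-dose pattern
  survives, the per-region ΔCOV signs are noise-dominated.
* At the full default resolution the simulated QSD runs at ~7% of the
  liver mean (vs ~4% physically, with the default per-slice counts), so
  borderline interface errors stay under threshold and the
  interface-enrichment signature is attenuated there; it is stable at the
  reduced-resolution study conditions under which it is asserted.
* Slice-stacked 2-D parallel-beam geometry; no TOF, helical path, scatter,
  randoms or decay — all orthogonal to the AC question by design.
* The lung tumour covers few voxels on coarse grids; its OSEM convergence
  is slow and its ROI uses the maximum, not the mean.
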