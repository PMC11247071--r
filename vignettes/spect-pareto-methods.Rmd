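---
title: "Bias-precision optimization of quantitative Lu-177 SPECT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-precision optimization of quantitative Lu-177 SPECT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative SPECT of ^177^Lu underpins dosimetry in molecular
radiotherapy: the treatment-relevant quantity is the activity
concentration (MBq/mL) in tumours and organs, estimated from
reconstructed images. Two error sources oppose each other. Systematic
error (bias) comes mainly from the camera's limited spatial resolution —
partial-volume effects depress the mean concentration of small hot
regions — and shrinks as OS-EM reconstruction accumulates updates.
Random error (noise), summarized as the coefficient of variation (CV) of
the estimate over repeated acquisitions, grows with updates and with
shorter acquisition times. No single setting minimizes both, so the
meaningful output is the *Pareto front*: the set of
(acquisition, reconstruction) settings for which bias cannot be reduced
without worsening CV, or vice versa.

`spectpareto` reimplements this optimization study as a self-contained
simulation pipeline. Everything is generated internally: voxelized
phantoms, an analytic projector with attenuation, distance-dependent
collimator blur and additive scatter, Poisson or bootstrap noise
realizations, OS-EM reconstruction under a constrained subset/iteration
scheme, cylinder-based calibration, volume-preserving VOI
quantification, and Pareto-front extraction.

## The stated world

The phantoms and protocol follow the printed study conditions:

* **Sphere phantom**: six spheres of 0.52, 1.15, 2.72, 5.61, 11.7 and
  26.9 mL at 5.80 MBq/mL in a cold water-filled body, imaged with 120
  projections over 360° at 180 s per projection, binned into 1-s time
  bins (the list-mode surrogate). The camera sensitivity is anchored so
  the phantom produces ≈700 counts/s aggregate in the photopeak window,
  which fixes the noise level of every downstream experiment.
* **Bootstrap**: reduced acquisitions with 20, 24, 30, 40, 60 or 120
  projections and 10, 20 or 40 min total virtual time are generated by
  pixel-wise resampling of time bins with replacement (k = time/N bins
  per pixel), 32 realizations per setting at full protocol. Pixels and
  angles resample independently; bin values need not be integers.
* **Anthropomorphic arm**: ellipsoidal liver, spleen and kidneys plus
  three spherical tumours (2.8, 8.9, 40.0 mL) at the printed
  concentrations for 24 h and 168 h post injection (tumours 1.9 and
  0.75 MBq/mL); noise enters as Poisson draws on noise-free projections.
* **Reconstruction schemes**: the number of subsets must be an even
  integer divisor of the projection count with at least two angles per
  subset, and iterations × projections ≤ 2400 (a stand-in for a fixed
  reconstruction-time budget). Across the six projection counts this
  yields 1900 settings; images are snapshotted after every iteration.
* **Calibration**: a uniform cylinder (radius 10.8 cm, length 18.6 cm;
  22.8 kBq/mL) reconstructed noise-free with every scheme; the factor is
  the reference concentration over the mean signal in a central
  cylindrical VOI (375 mL sphere arm, 1953 mL anthro arm).
* **Evaluation**: per setting and VOI, the absolute mean relative error
  |C̄~est~/C~ref~ − 1| and CV = s/C̄~est~ over realizations (sample SD,
  n − 1). Settings whose mean estimate is zero have undefined CV and are
  excluded; estimates deviating more than 50 % from the median are
  flagged as outliers but retained. Plots and fronts include only
  settings with ≥ 2 iterations and ≥ 16 updates.

## The forward model

The projector is a rotation-based parallel-beam approximation of a
medium-energy parallel-hole collimator at 208 keV. Per angle the volume
is rotated into the detector frame (bilinear interpolation in the
transaxial plane), each voxel is weighted by
exp(−∫μ dl) along the ray to the detector (μ in cm⁻¹, water 0.136 at
208 keV), each constant-depth plane is blurred with an isotropic
Gaussian of width σ(d) = √(σ₀² + (b·d)²), and depth planes are summed
and scaled by sensitivity × voxel volume, giving counts/s per pixel for
a concentration volume in MBq/mL. Scatter is an *effective convolution
model*: the primary projection convolved with a broad Gaussian and
scaled by f/(1−f), so scatter/total equals the configured fraction f for
a uniform field. Simulation and reconstruction share this scatter term
by default (a matched, model-based compensation in the spirit of
effective scatter-source estimation; the true ESSE kernel is out of
scope).

The back projector is the exact matrix transpose of the forward
projector — the bilinear gather is mirrored by a bilinear scatter with
identical weights, and the symmetric zero-padded convolutions are
self-adjoint — which the test suite verifies against a dense matrix
built column by column. Exact adjointness is what makes the ML-EM
likelihood-monotonicity and fixed-point properties hold to numerical
precision.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `voxel_mm` | 4.42 | isotropic voxel/pixel size (clinical matrix) |
| `orbit_mm` | 250 | rotation centre to collimator face |
| `sigma0_mm` | 1.7 | intrinsic resolution σ |
| `slope` | 0.043 | blur σ growth per mm distance (≈11 mm FWHM at 100 mm) |
| `sensitivity_cps_MBq` | anchored | counts/s per MBq; set via `calibrate_sensitivity()` to hit 700 counts/s |
| `scatter_fraction` | 0.15 | scatter-to-total in the 208 keV window |
| `scatter_width_mm` | 40 | σ of the effective scatter kernel |
| `mu_water` | 0.136 cm⁻¹ | body attenuation at 208 keV |

The PSF and sensitivity of the physical camera are not published;
σ₀ = 1.7 mm with slope 0.043 is representative of medium-energy
collimators, and the count-rate anchor — not an absolute sensitivity —
is what ties the simulation's noise level to the measured study. The
scatter fraction (0.15) and kernel width (40 mm) are likewise
representative values for ^177^Lu photopeak imaging with a 15 % window;
they were chosen once, before any acceptance outcome was measured, and
are configurable.

## OS-EM

The update is the classic multiplicative one per subset S,
f ← f/(Aₛᵀ1) · Aₛᵀ(pₛ/(Aₛf + sₛ)), with the additive scatter estimate
sₛ in the denominator. Projections are divided by the time per
projection first, so reconstructions are in count-rate units and the
calibration factor carries the conversion to MBq/mL. Choices the
protocol leaves open:

* **Initialization**: uniform inside the attenuation support at the
  data-implied mean concentration. Scaling the start value with the data
  keeps OS-EM exactly scale-equivariant at every iteration, which makes
  calibrated estimates independent of the calibration-phantom
  concentration to machine precision.
* **Subset order**: natural interleaved order (subset i takes angles
  i, i+S, …), not bit-reversed; deterministic and simple, but a known
  deviation risk relative to unknown vendor orderings.
* **Zero guards**: the forward projection is clamped at 10⁻¹² of its
  mean before division; voxels with zero subset sensitivity are left
  unchanged. All-zero projection sets return a zero image with a
  warning, mirroring the degenerate case the evaluation rules exclude.
* **ML-EM**: a single subset is admitted as a special case for analysis
  and testing (likelihood monotonicity); the scheme enumeration itself
  only ever emits the even-divisor subsets.

## VOI definition

Phantom regions and evaluation VOIs share one voxelization rule: voxels
are ranked by their overlap fraction with the analytic shape (estimated
with 4× subvoxel sampling per axis) and included greedily until the mask
volume is as close as possible to the target, guaranteeing agreement
within one voxel. Because the same rule defines the hot regions and the
VOIs, reference and estimate always refer to the same physical volume —
the analogue of transferring digital-phantom masks into the image grid
volume-preservingly.

## What the generator emulates — and what it does not

The synthetic acquisition reproduces the features that drive the
bias-precision trade-off: Poisson counting statistics at the measured
aggregate rate, depth-dependent resolution loss, attenuation, a broad
scatter background, angular sampling, and virtual-time scaling. It does
not model septal penetration, dead time, detector nonuniformity,
energy-window spectroscopy, non-circular orbits, patient anatomy beyond
geometric organs, or photon-transport physics; and by default the
reconstruction model is *matched* to the simulation (model mismatch can
be emulated by reconstructing with a `spect_system()` whose PSF or
scatter parameters differ from the simulation's, and by passing a
perturbed `scatter_estimate`).
Green tests therefore establish the internal consistency of the
pipeline and the reproduction of the protocol's bookkeeping and
statistical structure at desk scale — not agreement with any specific
physical camera.

## Numerical choices

* Blur kernels are truncated at 3.5σ and normalized; rotation uses
  bilinear interpolation with out-of-grid reads as zero.
* A band-limited source (Gaussian blob) is the test object for
  rotational symmetry: an on-grid delta acquires direction-dependent
  interpolation smoothing of order 20 %, which is a property of every
  linear-interpolation rotator, not a defect of this one.
* Bootstrap draw counts k beyond twice the acquired bins trigger a
  warning (the emulated protocol never exceeds the acquired 180 s).
* Pareto domination uses non-strict ≤ in both coordinates with at least
  one strict <; coordinate ties share front membership. Fronts are
  computed per VOI and acquisition time (and time point, anthro arm),
  pooling projection counts and schemes.
* All randomness flows from one root seed through deterministic child
  seeds (kept below 2³¹), so arm runs are byte-reproducible.

## Desk-scale defaults

The full printed protocol (1900 settings × 32 realizations × 3 times)
is hours of compute. `sphere_arm_config()` / `anthro_arm_config()`
default to a reduced sweep (two projection counts, one time, subsets
{2, 4, 10}, ≤ 12 iterations, 8 realizations) on the full-size
64×64×48 grid, and `full = TRUE` restores the complete protocol. The
qualitative structure the study reports — CV rising as acquisition time
falls, low-subset settings at the low-CV/high-bias end of the front,
high-subset settings at the low-bias/high-CV end, and the limited
influence of the projection count — is reproduced at desk scale by the
acceptance suite.

## Known limitations

* The projector is parallel-beam with a circular orbit; real cameras
  use non-circular orbits, which modulate the depth-dependent blur.
* The effective scatter kernel is stationary across the field of view,
  unlike object-dependent scatter estimates.
* Organ/tumour positions in the anthropomorphic phantom are documented
  stand-ins; only volumes and concentrations are anchored to the study.
* With 16–32 realizations the CV itself carries a relative standard
  error above 10 % (1/√(2(n−1))), so single CV values should be read
  with that uncertainty in mind — one of the study's own caveats.
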