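---
title: "nucdyn: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nucdyn: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucdyn)
```

## The problem

In mouse cells the major-satellite repeats cluster into DAPI-dense
chromocenters — pericentromeric heterochromatin (PCH). PCH replicates in a
defined window of S phase, and histone-modification dynamics around that
window (enrichment before replication, loss afterwards) can be read out
quantitatively from multichannel 3D fluorescence stacks. `nucdyn`
implements the full measurement chain: nucleus and chromocenter
segmentation, voxelwise chromatin-compaction classification, replication-
foci (RFi) detection and mapping, S-substage scoring, colocalization,
high-content cell-cycle gating, and FRAP kinetics — together with a
synthetic-data module that generates all of these inputs with exact ground
truth, so that every stage is testable without any microscopy data.

## Image model and preprocessing

All stacks are `(z, y, x)` arrays with voxel spacing in µm
(`image_stack()`). Filters are separable and use reflective borders, fixed
for reproducibility:

* `gaussian_smooth(stack, sigma)` — sampled-Gaussian kernel truncated at
  3.5 sigma; sigma is in voxels per axis (scalar = isotropic in voxel
  units). Sigma 1 is the default before chromocenter segmentation, sigma 2
  before nucleus segmentation.
* `mean_smooth(stack, radius)` — cubic box mean; radius 1 (a 3×3×3 mean)
  precedes spot seed detection.
* `normalize_contrast(stack)` — min–max rescale to [0, 1] with 0%
  saturation.

Native intensities are kept throughout; nothing is quantized to 8-bit, so
thresholds computed on the data are exact rather than bin-rounded.

## Segmentation

`segment_nucleus()`: Gaussian blur (sigma 2), min–max normalization, a
global threshold (Otsu on a 256-bin histogram by default), then 2
dilations, 3D hole filling and 2 erosions, keeping the largest 6-connected
component. One nucleus per crop is assumed. On a noise-free simulated
ellipsoid the mask volume is within 5% of the analytic voxel count.

`segment_chromocenters()`: Gaussian blur (sigma 1), a threshold computed
*within* the nucleus, connected components, and size selection
(`min_size = 50` voxels by default; no upper bound). The default threshold
rule is **halfmax**: halfway between the nucleoplasm level (nuclear
median) and the chromocenter level (mean of the brightest 0.5% of nuclear
voxels). The reason is class imbalance: chromocenters occupy only a few
percent of the nuclear volume, and variance-based histogram rules (Otsu,
1D 2-means) then land close to the nucleoplasm mode; on simulated nuclei
(nucleoplasm 1000, PCH 3000 a.u.) Otsu sits near 1430, which keeps the dim
blur halo, fuses adjacent chromocenters and dilutes the PCH enrichment
ratio from 2.0 to ~1.65. The halfmax rule lands near 2000, the blurred-edge
midpoint, recovering object counts and enrichment exactly. Otsu and a
fixed top-quantile rule (which is invariant to monotone intensity
transforms) remain available via `threshold=`.

## Chromatin compaction classes (HMRF)

`classify_compaction_hmrf()` partitions nuclear voxels into
`n_classes = 7` compaction classes from DNA intensity using a hidden
Markov random field: Gaussian emissions per class and a Potts smoothness
prior of strength `beta` over the 6 face neighbours. Optimization is
iterated conditional modes with EM-style updates:

1. initialize labels by quantile binning into equal-count classes
   (deterministic — no k-means seed sensitivity);
2. re-estimate class means and variances from the current labels;
3. synchronously re-assign every voxel to the class minimizing
   (negative log emission) − beta × (weighted count of agreeing
   neighbours);
4. stop when fewer than `tol = 0.1%` of labels change or after
   `max_iter = 50` sweeps.

Defaults: `beta = 0.3`, per-axis neighbour weights proportional to inverse
voxel spacing (so weak axial coupling under z-anisotropy). Classes are
relabelled by ascending emission mean, class 1 = least dense chromatin;
classes 1–4 form the active nuclear compartment (ANC), classes 5–7 the
inactive compartment (INC). The returned `class_means`/`class_vars` are the
emission parameters of the final sweep, so with `beta = 0` the labels are
*exactly* the per-voxel Gaussian maximum-likelihood assignment under the
returned parameters — a property the test suite asserts against an
independent ML computation. We expose MAP labels (and ICM pseudo-
posteriors), and make no claim of numeric identity with any other HMRF
implementation.

Signals map to classes by `map_signal_to_classes()`: voxels above a
threshold (Otsu within the nucleus by default) contribute their
*intensity* to their voxel's class; the profile is the per-class fraction
of total supra-threshold intensity, so bright foci weigh more than dim
haze. Profiles sum to 1 within 1e-9 by construction.

## 3D spot detection

`find_seeds()` → `grow_spots()` → `watershed_split()` →
`count_spots_in_roi()`:

* Seeds are strict 26-neighbourhood local maxima inside the nucleus on the
  mean-filtered, normalized stack, with prominence over the nuclear median
  of at least `noise_tolerance` (default 3× the MAD of nuclear voxels), and
  non-maximum suppression within `merge_radius = 2` voxels. Voxels on the
  array faces are excluded: under reflective smoothing, border noise is
  under-averaged and face voxels trivially dominate their missing
  neighbours, which otherwise produces spurious maxima.
* Each spot grows by 6-connected flood fill from its seed over voxels at or
  above a stop threshold derived from a 1D Gaussian fit
  (A·exp(−r²/2σ²) + B) to the radially averaged profile within
  `fit_radius = 7` voxels (anisotropy-scaled shells):
  threshold = B + `stop_fraction`·A, with `stop_fraction = 0.5`
  (half maximum above offset). A flat profile discards the seed with a
  logged reason; a failed fit falls back to the window half-range.
* Regions claimed by several seeds merge into multi-seed spots;
  `watershed_split()` separates them by descending-intensity immersion
  from the seeds, preserving the voxel union exactly and conserving
  integrated intensity.
* Counting in an ROI uses centroid containment by default ("total spots in
  PCH" semantics); any-overlap is available.

On benchmark fields of 200 planted Gaussian spots (SNR 5, ≥6-voxel
spacing) precision and recall are ≥ 0.95 at a 2-voxel match radius.

## Cell-cycle gating and PTM normalization

`gate_population()` reproduces the classic DAPI/EdU gate: EdU-positive
cells are S; EdU-negative cells split into G1 (2C) and G2 (4C) by total
DNA. Thresholds are data-driven by default (Otsu on log EdU; the midpoint
of a deterministic 2-means split of log DNA among EdU-negative cells),
which makes the gate invariant to global linear intensity rescaling;
fixed thresholds (e.g. mean + 3 sd of a negative-control well) can be
supplied. Non-separable DAPI modes raise a `GateFailure` with diagnostics.

`ptm_fold_change()` divides each cell's PTM sum by its DNA sum (per cell,
before aggregation), takes the per-stage median of this ratio, and
normalizes to the G1 median — so the G1 fold is exactly 1 and the S/G2
folds estimate the modification's cell-cycle dynamics. The median was
chosen over the mean for robustness to segmentation outliers.

`measure_enrichment_in_roi()` returns Σ channel / Σ DNA over an ROI
(PCH enrichment) or the plain ROI mean (mean-EdU-in-PCH style measures).

## S-substage pattern and pulse-chase scoring

`classify_rfi_pattern()` computes two intensity-weighted fractions over
detected foci: `f_cc`, the fraction of total foci intensity whose
centroids lie in (2-voxel-dilated) chromocenters, and `f_rim`, the
fraction in the peripheral shell — the outer 15% of the normalized nuclear
radius. The normalized radius comes from a second-moment ellipsoid fit of
the nucleus mask (for a solid ellipsoid, coordinate variance = semiaxis²/5),
which keeps the shell's *relative* thickness in every direction even for
anisotropic nuclei; an erosion-depth shell would be set by the shortest
axis alone. Decision rule: `f_cc ≥ 0.4` → S II (chromocenter-associated
replication); else `f_rim ≥ 0.4` → S III (peripheral); else S I
(dispersed euchromatic). The thresholds are package decisions — the
original patterns were scored visually — and are validated against
simulator truth only; fewer than `min_foci = 5` foci is `Unclassifiable`.

`assign_pulse_chase_stage()` is the deterministic truth table over the
pulse (EdU, past synthesis) and chase (PCNA, ongoing synthesis) readouts:
(EdU−, PCNA+) → S I; (EdU+ with S I pattern, PCNA punctate) → S II, the
pattern read from PCNA; (EdU+, PCNA punctate−) → was S III at the pulse
and has exited S; (EdU−, PCNA−) → non-S. Pattern labels supplied for a
channel flagged absent are rejected.

## Colocalization

`manders_coefficients()` computes M1/M2 inside the nucleus mask with
per-channel thresholds (Otsu within the ROI by default; quantile and fixed
thresholds for reproducibility): M1 = fraction of channel-A supra-threshold
intensity inside channel B's supra-threshold mask, M2 symmetric. Both are
always reported. Channels with no supra-threshold intensity flag the
result `undefined`.

## FRAP

`normalize_frap()` double-normalizes: (ROI − background)/(nucleus −
background), then division by the pre-bleach mean — the whole-nucleus
denominator cancels acquisition bleaching and makes the result invariant
to linear intensity rescaling; normalization is idempotent.
`average_curves()` aligns replicates on a common time grid (linear
interpolation) and reports pointwise mean ± SEM; fits are intended for the
averaged curve. `fit_exponential_recovery()` fits
I(t) = I∞ − (I∞ − I₀)·exp(−t/τ) on post-bleach frames by
Levenberg–Marquardt least squares with data-driven starts (I₀ = first
post-bleach point, I∞ = mean of the last 10% of frames, τ from the time to
half recovery). The bleach defines t = 0 and is itself excluded; the first
post-bleach frame sits at t = dt, so the fitted I₀ extrapolates the true
bleach depth. Mobile fraction = (I∞ − I₀)/(1 − I₀), half-time = τ·ln 2.
A single-exponential model is the default; τ at its bounds or solver
failure returns `converged = FALSE` with the raw fit attached. A
two-component fit is deliberately not offered: with 10 s sampling and
10 min of recovery, typical chromatin FRAP data underdetermine it.

## What the simulator emulates — and what it does not

`simulate_nucleus_stack()` builds ellipsoidal nuclei (real mESC nuclei are
irregular; ellipsoids keep volumes analytic and tests exact) with
spherical chromocenters whose edges are blurred by 1 voxel to emulate
optics. Chromocenter centers are constrained to the ellipsoid shrunk by
(radius + 2) voxels per axis, with a 4-voxel surface-to-surface gap so
blur halos of adjacent objects cannot fuse. Replication-foci channels
follow the three substage geometries: S I — foci dispersed in the
nucleoplasm excluding (2-voxel-dilated) chromocenters; S II — foci planted
exactly on chromocenter surfaces; S III — foci in the peripheral shell
(normalized radius 0.85–0.96). The PTM channel is DNA-proportional with a
configurable fold enrichment inside chromocenters, so the planted
enrichment equals the expected Σ PTM/Σ DNA ratio over the PCH exactly.
Noise is Gaussian read noise (default 2% of the chromocenter level) plus
optional Poisson scaling, applied last. Defaults for voxel size
(0.2 × 0.04 × 0.04 µm) are simulator conventions, not measured values.

Not modelled: nucleoli (so the perinucleolar part of the S III pattern is
absent — rim only), photophysics (blinking, PSF z-asymmetry), cytoplasm,
touching nuclei in 3D, or live-cell time series. Passing tests therefore
demonstrate correctness of the measurement chain on geometrically ideal
nuclei, not robustness to every real-data pathology; the high-content
entry points accept per-cell tables from any external segmenter.

`simulate_population_table()` allocates stages deterministically
(largest-remainder rounding of the proportions; default 15/70/15%
G1/S/G2, the ~70% S fraction characteristic of mESC cultures) and draws
only the features stochastically: G1 ≈ 2C and G2 ≈ 4C DAPI (5% CV),
S uniform between 2C and 4C, EdU elevated in S only, and a per-stage PTM
enrichment factor with lognormal cell-to-cell scatter.
`simulate_frap_curve()` samples 6 pre-bleach and 60 post-bleach frames at
10 s (1 min before, 10 min after the bleach) from the closed-form recovery
model with acquisition bleaching applied to both raw traces.
`simulate_compaction_texture()` quantile-bins a smoothed Gaussian random
field into 7 equal-count, spatially coherent classes (correlation length
2.5 voxels) with Gaussian intensity noise at 10% of the class spacing.
`simulate_spot_field()` places Gaussian spots on a jittered grid with a
guaranteed minimum spacing over a flat noisy background.

## Numerical choices and degenerate inputs

* Thresholding uses Fiji-style 256-bin Otsu histograms; constant inputs
  warn and return zeros (`normalize_contrast`) or raise typed errors
  (`NoForeground`, `DegenerateHistogram`, `EmptySignal`, `GateFailure`,
  `Unclassifiable`).
* Connected components, hole filling and morphology are 6-connected,
  vectorized label-propagation implementations; the watershed is a
  descending-intensity immersion from seeds, which preserves voxel unions
  exactly.
* HMRF variance floors at 1e-8 of the nuclear variance prevent emission
  collapse; empty classes re-seed at spread quantiles.
* Ties in ICM class assignment and in local-maxima suppression break
  deterministically (first index / brightest first), so all outputs are
  reproducible bit for bit under a fixed seed.
* Cliff's delta uses the exact pairwise formula up to 4×10⁶ pairs and an
  equivalent rank-based O((n+m)·log) path beyond.

## Problem sizes

The bundled tests and the acceptance script run on deliberately modest
sizes chosen as representative rather than exhaustive: 64³ voxel textures
for the HMRF benchmark, 32×64×64 nuclei with 8 chromocenters and 40 foci
for pipeline-level checks, 200-spot detection fields, 2000-cell
populations, 66-frame FRAP traces, and 12-nucleus end-to-end batches.
All stochastic checks fix their seeds.
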