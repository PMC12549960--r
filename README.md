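# nucdyn

Quantitative 3D imaging of pericentromeric heterochromatin (PCH)
replication dynamics.

In mouse nuclei, major-satellite repeats cluster into DAPI-dense
chromocenters that replicate in a defined window of S phase. Measuring how
histone modifications, replication foci and transcription machinery
distribute over these structures — per cell, per cell-cycle stage, in 3D —
requires a long chain of image quantification. `nucdyn` implements that
chain for R users working with multichannel z-stacks and high-content
feature tables:

* **Segmentation** — 3D nucleus masks (Gaussian blur → threshold →
  morphological closing → largest component) and chromocenter/PCH objects
  (blur, in-nucleus threshold, size-based selection).
* **Chromatin compaction classes** — a hidden Markov random field (HMRF)
  over nuclear voxels: Gaussian emissions per class plus a Potts smoothness
  prior, optimized by iterated conditional modes,
  `argmin_k [ −log N(x_v; μ_k, σ_k²) − β · Σ_{u∈N(v)} w_u · 1{l_u = k} ]`,
  giving 7 classes ordered by DNA density (classes 1–4 = active nuclear
  compartment ANC, 5–7 = inactive compartment INC).
* **Signal-to-class mapping** — intensity-weighted class fractions for any
  channel (replication foci, histone PTMs), the rows of compaction-class
  heatmaps.
* **3D spot detection** — local-maxima seeds, a radial Gaussian fit per
  seed to derive the stop threshold (B + A/2), flood-fill growth, seeded
  watershed splitting of clustered spots, and centroid-in-ROI counting.
* **Cell-cycle analysis** — DAPI/EdU gating into G1/S/G2,
  DNA-normalized G1-referenced PTM fold changes, PCH enrichment ratios
  (Σ channel / Σ DNA over the PCH), S-substage classification of
  replication-foci patterns (S I dispersed, S II chromocenter-associated,
  S III peripheral), and the EdU/PCNA pulse-chase truth table.
* **Colocalization** — Mander's M1/M2 inside the nucleus with per-channel
  thresholds.
* **FRAP** — double normalization (whole-nucleus and pre-bleach),
  replicate averaging with SEM, and single-exponential recovery fits
  `I(t) = I∞ − (I∞ − I₀)·e^(−t/τ)` with mobile fraction
  `(I∞ − I₀)/(1 − I₀)`.
* **Statistics** — pairwise Wilcoxon / Welch t / ANOVA + Tukey HSD via the
  standard R routines, plus Cliff's delta from its defining formula.
* **Synthetic ground truth** — a simulator for nuclei with chromocenters,
  substage-patterned foci, PTM enrichment, cell populations (~70% S phase,
  the mESC regime), compaction textures, spot fields and FRAP traces, so
  the whole pipeline is testable without microscopy data.

## Worked example

```r
library(nucdyn)

# a simulated S II nucleus: 12 chromocenters, EdU foci on their surfaces,
# a PTM channel enriched 2-fold in PCH, 2% read noise
cfg <- sim_nucleus_config(s_pattern = "SII", ptm_cc_enrichment = 2, seed = 1)
sim <- simulate_nucleus_stack(cfg)

nucleus <- segment_nucleus(sim$channels$DNA)
pch     <- segment_chromocenters(sim$channels$DNA, nucleus)
pch
#> LabelMap: 40 x 80 x 80 voxels, 11 object(s)
```

Eleven of the twelve planted chromocenters survive — the smallest
(radius 2.9 voxels) falls below the default 50-voxel size filter after
optical blur, which is exactly what the size-based selection is for.

```r
cmap <- classify_compaction_hmrf(sim$channels$DNA, nucleus)
cmap
#> CompactionMap: 7 classes, means 913.3, 961.2, 990.9, 1018, 1049, 1102, 1824,
#>   converged=TRUE (31 sweeps)

edu   <- apply_mask(sim$channels$EdU, nucleus)
seeds <- find_seeds(edu, nucleus)
proc  <- attr(seeds, "processed")
foci  <- watershed_split(grow_spots(proc, seeds, nucleus = nucleus), proc)

profile <- map_signal_to_classes(edu, cmap)
round(as.numeric(profile), 3)
#> [1] 0.004 0.007 0.013 0.019 0.027 0.097 0.831
summarize_anc_inc(profile, cmap$anc_classes)
#> anc_fraction inc_fraction
#>   0.04416163   0.95583837
```

96% of the EdU intensity maps to the inactive nuclear compartment — the
S II signature of replicating pericentromeric heterochromatin. The
substage call and the PCH measurements agree with the planted truth:

```r
classify_rfi_pattern(foci, nucleus, pch)
#> [1] "SII"        (f_cc = 0.926)
measure_enrichment_in_roi(sim$channels$PTM, sim$channels$DNA, pch)
#> [1] 1.999        # planted 2.0x PCH enrichment
count_spots_in_roi(foci, pch)$total
#> [1] 13           # foci whose centroids fall inside PCH objects

fit <- fit_exponential_recovery(
  simulate_frap_curve(sim_frap_config(noise_sd = 0.02, seed = 1))$curve)
fit
#> FRAP fit: I0 = 0.219, plateau = 0.683, tau = 51.4 s,
#>   mobile fraction = 0.595, t1/2 = 35.6 s   # planted tau 50 s, mobile 0.6
```

Batch processing goes through `run_pipeline()` (YAML or list configs,
simulated or TIFF input, byte-reproducible CSV outputs) and
`compare_conditions()` for the group statistics; a thin command-line
wrapper lives at `inst/scripts/nucdyn` (`simulate` / `pipeline` / `frap`).
See `vignette("nucdyn-methods")` for the models, parameter meanings and
design decisions.

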