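---
title: "Radiomic risk scoring of tumor mass effect: models and methods"
author: "rampmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic risk scoring of tumor mass effect: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampmri)
```

## The problem

Pediatric medulloblastoma shows wide outcome disparities even within
established clinicopathological (Chang) and molecular (WNT, SHH, Group 3,
Group 4) risk strata. `rampmri` implements a radiomic risk score that
quantifies three complementary aspects of tumor biology visible on routine
MRI:

1. **Mass effect** — the displacement of normal parenchyma by tumor growth,
   read from the displacement field of a diffeomorphic registration of the
   subject brain to a healthy reference atlas;
2. **Intra- and peri-tumoral texture heterogeneity** — per-voxel texture
   maps inside the tumor sub-compartments;
3. **Morphology** — local surface curvature and global contour shape of
   each sub-compartment.

The tumor is described by three expert-segmented sub-compartments: the
enhancing lesion (`En`), peri-tumoral edema (`Ed`), and non-enhancing tumor
plus cystic core (`NC`); their union is the tumor *habitat* (`H`). The
parenchyma is the brain mask minus the habitat. Registration itself, bias
correction, and segmentation are consumed as interfaces: the package reads
their outputs (NIfTI volumes and 3-component displacement fields in mm) and
starts from there.

## Deformation-heterogeneity descriptor (192 features)

The parenchyma is divided into `m = 12` annular bands of width `w = 5` mm —
a standard clinical target-volume margin — by the exact anisotropic
Euclidean distance transform of the habitat, measured in physical mm so
that voxel spacing is honoured. Band `a` holds parenchyma voxels with
`(a-1)w <= d < aw` (half-open bins; the boundary convention is ours, as the
source accounting does not state one). Bands are clipped to the brain mask
and the loop always runs over all 12 bands so that the descriptor length is
constant across subjects; empty bands contribute a zero fill.

Within each band we summarize:

* **Magnitudes** `|u(c)|` (mm): mean, median, sample SD, Fisher skewness,
  excess kurtosis — 5 values per band (60 total);
* **Angles** `theta = arccos(x . y / |x||y|)` between the displacement `x`
  and the vector `y` from the voxel to the tumor centroid: the same 5
  statistics (60 total);
* **Angle histogram** over six fixed 30-degree intervals
  `[0,30), ..., [150,180]` — raw counts by default (72 total).

With `y` pointing *toward* the centroid, outward displacement (mass effect)
gives `theta` near 180 degrees and inward displacement near 0. An arccos
cannot produce signed angles, so rather than inventing a sign convention we
keep `theta` in `[0, 180]` and let the model read direction from the
histogram bins; the synthetic phantoms confirm that purely outward fields
land exclusively in the `[150,180]` bin and purely inward fields in
`[0,30)`. Voxels with `|x|` or `|y|` below 1e-8 mm enter the magnitude
statistics (as 0 where applicable) but are excluded from angle statistics
and histograms.

The result is a `12 * (5 + 5 + 6) = 192`-dimensional vector split
60/60/72. Bands default to the analyzed region's outer surface (so each
region carries its own mass-effect profile); a config switch
(`bandReference = "habitat"`) measures every region's bands from the
habitat edge instead.

## Texture descriptor (214 maps, 1070 features)

Five families total exactly 214 per-voxel maps; the composition within the
published total is a documented, configurable choice
(`textureParams()`):

| family   | maps | construction |
|----------|------|--------------|
| gradient | 5    | spacing-aware central differences: dx, dy, dz, magnitude, Laplacian |
| Haralick | 39   | 13 co-occurrence statistics x window sizes {3, 5, 7} |
| Laws     | 125  | all separable 3D combinations of L5/E5/S5/W5/R5 |
| Gabor    | 32   | 8 orientations x 4 wavelengths, per axial slice |
| CoLlAGe  | 13   | co-occurrence statistics of dominant local gradient orientations |

Numerical conventions: gray levels for co-occurrence are 64 equal-width
bins over the in-mask intensity range; co-occurrence matrices are
symmetric and direction-averaged over the 13 unique 3D directions, with
windows clipped at the mask/volume border; all convolutions use reflect
padding; Gabor kernels are DC-corrected so constant images give zero
response, and responses are quadrature magnitudes. CoLlAGe follows its
original per-slice (2D) formulation: the dominant orientation at a voxel
is the principal component of the gradient vectors over the local window
(computed via the windowed structure tensor), quantized to 8 orientation
bins over `[0, pi)`; windows without gradient energy are flagged
degenerate and report 0. Each map is summarized over a region with the
shared five statistics, giving `214 * 5 = 1070` features per region per
protocol. Intensities are z-scored within the brain mask beforehand; the
pipeline normalizes in the frame the inputs arrive in (if scans are
warped to atlas space upstream, texture is computed there — the package
does not resample).

## Shape descriptor (34 features)

Local surface shape uses the principal curvatures `k1 >= k2` (1/mm) of the
region's implicit surface: the binary mask is smoothed with a separable
Gaussian (sigma = 1.5 voxels by default) and mean/Gaussian curvature are
evaluated at surface voxels from spacing-aware first and second
derivatives of the level-set function. We chose the implicit (level-set)
formulation over an explicit mesh-plus-quadric-fit because it is meshless,
robust to pathological topologies, and directly validated against the
analytic sphere: digital spheres of radius 10 mm recover curvedness
`1/r` within a few percent (the test budget allows 15% for voxelization).
Four local features — curvedness `sqrt((k1^2+k2^2)/2)`, sharpness
`(k1-k2)^2`, shape index `(2/pi) atan((k1+k2)/(k1-k2))` with umbilic
convention `sign(k1+k2)`, and total curvature `k1^2+k2^2` — are each
summarized with the five statistics (20 values).

Fourteen global features complete the block: volume; major/minor axis
lengths `2*sqrt(5*lambda)` from the second-moment ellipsoid; eccentricity;
elongation `a2/a1`; orientation of the major axis versus the grid z-axis;
perimeter (surface area via the coarea integral of the smoothed mask);
roundness `pi^(1/3)(6V)^(2/3)/A`; equivalent spherical radius and
diameter; flatness `a3/a2`; elongation shape factor `a1/a3`; compactness
`36 pi V^2 / A^3`; and integrated intensity. The exact formula variants
are pinned here because the attribute names alone do not determine them.
Shape is computed once per region, independent of protocol count.

## Integration and survival modeling

Per region, the integrated set `F_I` concatenates `F_B` and `F_T` for each
available protocol (fixed order Gd-T1w, T2w, FLAIR) plus `F_S` once:
`192*3 + 1070*3 + 34 = 3820` features with three protocols, `1296` with
Gd-T1w alone. Subjects with different protocol availability belong in
separate analysis cohorts rather than being imputed. Feature names encode
protocol, family, band/map, and statistic, so selected features remain
interpretable.

Modeling proceeds strictly train-first:

1. constant features are dropped, then a greedy **Spearman filter**
   (threshold 0.9, fixed column order) removes redundant features;
2. features are z-scored with training parameters and fed to a penalized
   Cox model (`glmnet`); for each elastic-net mixing `alpha` in the grid
   the regularization strength is chosen by 5-fold cross-validated partial
   likelihood, and the best `(alpha, lambda)` pair wins. `alpha = 1` is
   LASSO, `alpha = 0` ridge. Ties use Efron's method in the downstream
   univariable fits. Standardization before fitting and the fold count are
   our defaults (the source is silent on both);
3. the **risk score** is `sum_z co_z F_z` over the selected features; the
   dichotomization threshold defaults to the training-score median (the
   "threshold provided by the fitted model" is ambiguous; mean is a config
   alternative), and is frozen for test subjects along with the
   standardization, selection, and coefficients;
4. evaluation: Kaplan-Meier curves, two-sample log-rank test, hazard ratio
   with Wald 95% CI from a univariable Cox fit on the group indicator, and
   Harrell's C-index of the continuous score. Associations with clinical
   stratifications use McNemar's test (exact binomial variant below 25
   discordant pairs) and the Pearson chi-square test of independence.
   Log-rank p-values are reported raw; a Benjamini-Hochberg pass over
   multi-region runs is available via `stats::p.adjust` on the report.

The default `alpha` grid is `seq(0, 1, by = 0.02)`; the simulation-based
test suites use the coarser grids noted below to keep the default
configurations light.

## The synthetic phantom generator

Real multi-institutional cohorts behind this class of model are private,
so every stage is validated on synthetic subjects with known ground truth
(`phantomSpec()`, `generatePhantom()`, `generateCohort()`):

* nested ellipsoidal compartments `NC ⊂ En ⊂ Ed ⊂ brain` on a 40-voxel,
  3 mm isotropic grid (a 120 mm field of view — coarse but sufficient for
  several populated 5 mm bands around a 2–3 cm tumor);
* per-compartment intensities with protocol-typical contrasts plus a
  Gaussian random field (correlation length 4 mm, SD 0.15) for texture;
* an analytic displacement field `u(c) = s A exp(-d(c)/lambda) û(c)` with
  amplitude `A`, decay length `lambda` = 20 mm, distance-from-habitat `d`,
  and radial unit direction `û`; `s` is +1 (outward), -1 (inward), or a
  per-voxel random sign ("mixed"). Generating fields analytically rather
  than running a registration isolates descriptor correctness from
  registration behaviour;
* survival times from an exponential proportional-hazards model whose
  linear predictor applies the named true coefficients to standardized
  latent generator parameters (baseline median survival 24 months);
  censoring is administrative-uniform with the horizon calibrated by
  root-finding to the target censored fraction (default 30%);
* all randomness flows through one seed per subject, so cohorts are
  bit-reproducible.

Cohort defaults draw the amplitude uniformly from 0.5–6 mm — spanning
subtle to pronounced mass effect — with `beta = 1` per SD of amplitude as
the reference signal strength. What the phantoms deliberately do **not**
emulate: anatomy, MR physics (bias fields, partial volume, scanner
variation), registration error, or segmentation noise. Passing tests
therefore demonstrate correctness of the computational pipeline and
recoverability of a planted signal, not clinical performance.

## Problem sizes and seeds used by the test suites

The simulation suites run at sizes chosen to exercise the full pipeline
while keeping the default test configurations light: feature recovery uses
n = 300 subjects with 3 informative among 53 features over 20 seeds
(`alpha` grid {0.5, 1}); the end-to-end experiment uses a 200-subject
amplitude-driven cohort split 100/100 (`alpha` grid {0, 0.5, 1}, habitat
region, Gd-T1w protocol); null calibration reuses the extracted features
with 10 independent outcome draws at `beta = 0`. The acceptance script
(`scripts/acceptance.R`) re-runs all of these from scratch under a
user-supplied seed.

## Known limitations

* Angle statistics summarize an unsigned `[0, 180]` quantity; direction
  enters only through the histogram bins.
* The 214-map texture inventory is one defensible realization of the named
  families; alternative parameterizations change individual features (not
  the contract totals, which are recomputed from the configuration).
* Surface statistics on very small regions (tens of voxels) are dominated
  by voxelization; masks under 4 voxels are rejected outright.
* Multi-component regions are analyzed as their union.
* The exponential baseline hazard of the simulator is convenient, not
  clinical; C-indices on phantoms calibrate the machinery, not patients.
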