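# rampmri

Radiomic prognostic scoring of tumor mass effect on brain MRI.

Pediatric medulloblastoma outcomes vary widely even within the accepted
clinicopathological (Chang) and molecular (WNT/SHH/Group 3/Group 4) risk
strata. `rampmri` is for imaging scientists who want to build and validate
a complementary, image-derived risk score from routine MRI: it extracts
three radiomic descriptor families from segmented 3D volumes and
atlas-registration displacement fields, integrates them, and fits
penalized Cox proportional-hazards models that stratify subjects into
high- and low-risk survival groups.

## The model

Given tumor sub-compartments I_En (enhancing lesion), I_Ed (edema), I_NC
(non-enhancing + cystic core), their union I_H (the habitat), and the
parenchyma I_B = brain \ I_H:

* **Deformation heterogeneity, F_B (192-D)** — I_B is divided into m = 12
  annular bands of w = 5 mm by the exact Euclidean distance transform from
  the tumor edge. Per band: five statistics of the displacement magnitudes
  |u(c)|, five statistics of the angles θ = arccos(x·y / |x||y|) between
  each displacement x and the voxel-to-centroid vector y, and a 6-interval
  fixed-width angle histogram ([0°,30°), …, [150°,180°]) — 60 + 60 + 72
  values.
* **Texture, F_T (1070-D)** — 214 per-voxel maps (gradient 5, Haralick
  13 × windows {3,5,7}, Laws 125, Gabor 8 × 4, CoLlAGe 13), each
  summarized over a region with mean, median, SD, skewness, kurtosis.
* **Shape, F_S (34-D)** — five statistics of four local surface-curvature
  features (curvedness, sharpness, shape index, total curvature) plus 14
  global morphology attributes.

The integrated set F_I = [F_B, F_T per protocol; F_S] has
192·3 + 1070·3 + 34 = 3820 features with Gd-T1w/T2w/FLAIR, or 1296 with
Gd-T1w alone. After a greedy Spearman redundancy filter, an elastic-net
Cox model (α ∈ [0,1] and λ chosen by cross-validated partial likelihood)
selects features, and the risk score

RaMP = Σ_z co_z · F_γz

is thresholded at the training median to dichotomize subjects; evaluation
uses Kaplan–Meier curves, the log-rank test, hazard ratios with 95% CIs,
and Harrell's C-index. Because the clinical cohorts behind this design are
private, the package ships a synthetic phantom generator (nested
ellipsoidal tumors, radially decaying displacement fields, Cox-generated
survival) so every stage is verifiable with known ground truth.

## Worked example

```r
library(rampmri)

# one synthetic subject: volumes, segmentation, displacement field
ph <- generatePhantom(phantomSpec(amplitude = 4, seed = 42))
ph$seg
#> SegmentationMap: |En|=148 |Ed|=304 |NC|=32 voxels, brain 20168 voxels

# deformation descriptor over 12 annular 5-mm bands
hab   <- buildHabitat(ph$seg)
sp    <- spacing(ph$seg)
bands <- buildAnnularBands(hab, brainMask(ph$seg), sp)
fb    <- assembleFB(ph$field, bands, tumorCentroid(hab, sp))
length(fb)
#> [1] 192
round(fb[c("mag.band01.mean", "mag.band04.mean", "angbin.band01.bin6")], 3)
#>    mag.band01.mean    mag.band04.mean angbin.band01.bin6
#>              3.356              1.685            488.000

# full integrated feature set for the habitat (3 protocols)
feats <- extractSubjectFeatures(ph$scenes, ph$seg, ph$field,
                                rampConfig(regions = "H"))
length(feats$H)
#> [1] 3820

# a 60-subject cohort with amplitude-driven survival, 30/30 split
coh <- generateCohort(cohortSpec(n = 60, seed = 7))
cfg <- rampConfig(regions = "H", alphaGrid = c(0, 0.5, 1))
ex  <- runExtract(coh$phantoms, cfg, protocols = "GdT1w")
ids <- coh$survival$subject_id
rep <- runModel(ex$tables$H, coh$survival,
                list(train = ids[1:30], test = ids[31:60]), cfg)
rep$fit
#> RampCoxFit: alpha=0.5 lambda=0.5766, 7/873 features selected
#>   threshold (median rule): -0.001297
#>   top coefficients:
#>     GdT1w.FB.mag.band01.mean: +0.2136
#>     GdT1w.FB.mag.band09.mean: +0.1308
#>     GdT1w.FT.haralick.w7.sumAverage.skewness: -0.1038
#>     GdT1w.FT.laws.S5W5R5.median: -0.0805
#>     GdT1w.FB.mag.band11.sd: +0.0217
round(c(test_logrank_p = rep$test$logrank$p,
        test_cindex   = rep$test$metrics$cindex,
        test_hr       = rep$test$metrics$hr), 4)
#> test_logrank_p    test_cindex        test_hr
#>         0.0003         0.6797         7.7127
```

The first deformation band's mean magnitude (3.356 mm) reflects the
planted 4 mm amplitude decayed to the band's distance; 488 angle counts in
bin 6 ([150°,180°]) mark a purely outward (mass-effect-like) field. On the
held-out half the model separates the risk groups (log-rank p ≈ 3e-4) and
ranks survival with C ≈ 0.68; the leading selected features are
deformation magnitudes, i.e. the planted signal.

Real data enter the same way: `readVolume()`, `readSegmentation()`, and
`readDeformationField()` build the same objects from NIfTI files, and
`inst/cli/ramp.R` wraps simulate/extract/model for shell use.

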