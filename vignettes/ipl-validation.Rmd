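---
title: "Validating intraprostatic lesion contours against biopsy sectors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating intraprostatic lesion contours against biopsy sectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iplconcord)
```

## Scope and design

`iplconcord` re-creates, on synthetic data with known ground truth, the full
chain used to validate intraprostatic lesion (IPL) delineation from PSMA-PET
and multiparametric MRI against biopsy-derived sector landmarks:

1. a digital prostate phantom (`generate_case()`),
2. a 36-sector schematic of the gland with simulated systematic + targeted
   biopsy (`build_sector_map()`, `simulate_biopsy()`),
3. landmark registration of the schematic onto axial slices (`fit_rigid()`,
   `fit_deformation()`, `transfer_sectors()`),
4. automatic fractional-SUVmax contouring with dominant-lesion selection and
   margin expansion (`auto_contour()`, `select_dominant()`, `expand_margin()`),
5. sector-level overlap scoring and best-threshold selection
   (`sectorize_contour()`, `score_sectors()`, `best_threshold()`),
6. the statistical layer (`normality_screen()`, `compare_methods()`,
   `factor_correlation()`).

The package is organised tidyverse-style where the data are tabular — every
record, summary and statistical result is a tibble, the study object has
`tidy()`/`glance()`/`autoplot()` methods — while volumes, masks and warps are
lightweight S3 containers, since a 3D image is not usefully a data frame.

## The phantom

**Anatomy.** The gland is an ellipsoid with semi-axis ratios
(1, 0.85, 1.1) (lateral, antero-posterior, axial), discretized on a
56 × 56 × 24 grid at (1.5, 1.5, 3) mm spacing. Rather than thresholding the
ellipsoid at its nominal surface, the generator thresholds the normalized
radius field at the order statistic matching the target voxel count, so the
discretized volume hits the requested value (median 31 cc, truncated
log-normal on 21–54 cc) to within one voxel. Regions (apex/mid/base) are
equal thirds of the cranio-caudal mask extent, the three axial levels of the
schematic; the transition zone is a co-centred inner ellipsoid (62% in-plane,
95% axially), the peripheral zone the rest.

**Lesions.** Index lesions are ellipsoids of randomized axis ratios
intersected with the gland, again with an order-statistic iso-level so the
realized relative volume is exact. Defaults follow the reference cohort this
package is designed to stress: 1–2 index lesions per case, relative volume
median 18% on 6–75%, assigned SUVmax median 8.2 on 1.9–21.4, Gleason grades
6/7a/7b/8/9 with probabilities 0.23/0.17/0.14/0.28/0.18, PSA median
15.4 ng/mL on 0.6–57.9. In addition, 0–2 **satellite microfoci** per case
(0.5–4.5% of the gland, SUVmax 1.0–3.2) model the multifocality of prostate
carcinoma: biopsy cores can hit them, but their uptake sits near background,
so image-derived contours usually miss them. This is what makes
biopsy-positive locations exceed the imaged lesions and gives the sensitivity
its threshold dependence; without satellites every threshold scores
near-perfect sensitivity and the operating-point trade-off degenerates.

**Imaging.** The PET volume is background (0.7 SUV in-gland, 0.2 outside)
with lesion uptake overlaid using max semantics, so the pre-blur lesion peak
equals the assigned SUVmax exactly. The volume is then convolved with an
axis-aligned Gaussian PSF (FWHM 6 mm for ⁶⁸Ga, 5.5 mm for ¹⁸F — ¹⁸F tracers
have somewhat better physical resolution; MRI-like channels unblurred) and
degraded with zero-truncated Gaussian noise (SD 0.1 SUV). T2W and ADC render
lesions hypo-intense, DCE hyper-intense; these channels exist so the manual
mpMRI arm has something to be "read" from, not as MRI physics. What the
phantom does **not** emulate: reconstruction artefacts, heterogeneous
intra-lesion uptake, bladder spill-over, rectal/seminal anatomy, or true
reader psychology — passing tests demonstrate the *pipeline's* correctness
and calibration, not clinical performance on real images.

**Observer model.** `simulate_manual_contour()` warps the true mask by a
smooth random displacement field with RMS magnitude `observer_noise_mm`
(correlation length 6 mm). Defaults in `run_study()`: 1.5 mm for PET/CT
readers, 1.2 mm for PET/MRI (hybrid display, better anatomical anchoring),
3.0 mm for mpMRI; the mpMRI reader additionally misses a lesion with
probability `exp(-relvol/0.15)`, reproducing the lower sensitivity of
MRI-only reading for small foci.

## Sectors and biopsy

The 12 segments per level are 2 sides × 2 zones × 3 angular wedges
(anterior/lateral/posterior, breaks at ±30° from the lateral axis; the exact
12-segment geometry is not standardised, so the breaks are arguments). The
voxel assignment partitions the gland exactly; the schematic planes use a
48-gon outline whose sector polygons tile it without gaps, which is what
makes the registration step well-posed.

Each biopsy core is a needle track through the gland at a fixed
lateral/axial position (12 systematic positions: lateral and medial pairs per
region; targeted cores aim at lesion centroids). A core with tumour path
length $L$ detects the lesion with probability $1 - e^{-L/\lambda}$
($\lambda$ = 3 mm), a one-parameter model of why small foci are poorly
detected. Detected cores turn the traversed sectors positive, which inherit
the lesion's Gleason score; traversed sectors without detection are negative;
untraversed sectors are unsampled and count as negative when scoring
(configurable `unsampled = "exclude"`) — absence of a positive biopsy counts
against the contour. Targeted cores are drawn after the systematic ones, so
enabling targeting never changes the systematic draws at a fixed seed; this
makes the "targeting never loses detections" property exact, not just
stochastic.

## Registration

The manual two-step schematic-to-patient matching is replaced by its
algorithmic analogue: a least-squares rigid fit (translation + rotation,
optional isotropic scale for image-size differences) with correspondence
resolved by arc-length resampling and a circular-shift search (a `"paired"`
mode exists for known landmarks), followed by an **interpolating
thin-plate-spline** warp on control points sampled at matched arc-length
fractions of the two outlines. The interactive multipoint deformation of a
drawing program is not reproducible; an interpolating landmark warp is the
standard algorithmic stand-in and satisfies the same contract: every control
point maps exactly (residuals at solver precision, ~1e-12 mm), the warp is
continuous, and the identity is recovered when outlines coincide.
Registration is 2D per axial level, mirroring the section model; 3D
registration is out of scope. `transfer_sectors()` rasterises the warped
polygons with an even-odd point-in-polygon test; a gland voxel outside all
warped polygons (possible at chord edges) is assigned to the nearest polygon
and counted, never dropped. `run_study()` fits the schematic outline to each
region's central slice and records the rigid RMSD and post-warp outline
residual per case as a registration quality report.

## Contouring, margins, scoring

SUVmax is taken over the whole gland (the multi-focal per-focus variant is
behind `per_lesion_suvmax = TRUE`, since published practice is ambiguous for
multifocal cases); contours are 26-connected components of
$\{SUV \ge f \cdot SUV_{max}\}$ within the gland, or of an absolute
threshold (SUV 3.0). Dominant-lesion selection keeps volume ≥ 1 cc **and**
SUVmax ≥ 3, both inclusive. Margin expansion is morphological dilation by a
Euclidean ball in physical millimetres, implemented via an exact anisotropic
distance transform (compiled; the one place the package uses C++, alongside
3D component labelling, because no installed R package offers 3D
anisotropic morphology).

Scoring is **sector-level** — the reference standard is sectors, not voxels:
a sector is predicted positive when the 5 mm margin-expanded contour overlaps
it at all (τ = 0; a minimum overlap fraction is an argument). A voxel-level
Dice against the margin-expanded positive-sector volume is provided as a
secondary mode (`voxel_dice()`, with the margin applied to both structures by
default, or only the contour). The scoring unit is the dominant ground-truth
lesion; per-method aggregation reports mean ± SD with undefined metrics
(e.g. sensitivity with no positive sector) excluded pairwise and counted.
`best_threshold()` maximises mean DSC, verifies the Youden index agrees, and
otherwise returns the DSC maximiser with a flagged warning; ties fall back to
YI, then specificity.

Because fractional contours nest ($f_2 > f_1 \Rightarrow$ contour$(f_2)
\subseteq$ contour$(f_1)$) and dilation is monotone, the predicted sector set
shrinks as the threshold rises **per lesion**, so mean sensitivity is
non-increasing and mean specificity non-decreasing in the threshold — a
deterministic property of the pipeline, checked on a 30-case cohort in the
acceptance suite. Which threshold maximises DSC on a synthetic cohort depends
on the PSF width and margin and is *not* asserted to equal 70%.

## Statistics

Normality screening is a one-sample Kolmogorov–Smirnov test against a normal
with the sample's own mean/SD (conservative with estimated parameters, which
is acceptable for a screen); constant samples are flagged, not tested.
Method comparisons use Kruskal–Wallis; the all-tied case returns H = 0,
p = 1. Factor analysis correlates stratum membership indicators with
per-lesion DSC (point-biserial Pearson r with its t-test p-value). The
relative-volume strata are implemented as **"at least x%" threshold
indicators** (5/10/15/20%): reading them as cumulative "at most" strata would
invert the reported gradient, which rises because large lesions — above
roughly 15% of the gland — are delineated more accurately, so the threshold
reading is the coherent one and the labelling is configurable. Both-classes-present is
required; single-class indicators report `NA`. No multiple-testing correction
is applied by default (matching the exploratory framing of the reference
analysis); `p.adjust` can be applied downstream as the results are tidy
tibbles. A multivariate logistic regression layer is deliberately absent —
no outcome/covariate specification exists to implement.

`simulate_metric_cohort()` is a record-level generator (DSC as a logistic
function of relative volume plus noise, knee at 13%) used to calibrate the
factor-correlation layer: across 200 replicate cohorts of 30 lesions the
≥15% indicator out-correlates the ≥5% indicator in ≥ 99% of replicates. Its
relative-volume range extends below 5% deliberately, so the ≥5% stratum has
both classes — with the imaging phantom's 6–75% range that indicator would
be single-class.

## Numerical choices and problem sizes

- Coordinates: voxel `(i, j, k)` (1-based in R) has its centre at
  `((i−1)dx, (j−1)dy, (k−1)dz)` mm; the third axis is axial.
- Distance-transform comparisons use a 1e-9 mm slack so voxels exactly at
  the margin radius are included regardless of floating-point noise.
- Order-statistic iso-levels make generated masks hit target voxel counts
  exactly; gland centres get a sub-voxel jitter to break discretization ties.
- Per-case RNG streams are derived from `(cohort seed, case index)` via a
  fixed integer hash, so any case regenerates bit-identically in isolation.
- Test and acceptance problem sizes are chosen as the smallest that exercise
  each property cleanly: 30-case cohorts for trade-off and range checks,
  200 replicates for Monte-Carlo frequencies, 0.4–1 mm grids for the
  analytic contouring and margin oracles, exhaustive confusion-tuple
  enumeration up to totals of 20.

## Known limitations

- The phantom's uniform-uptake ellipsoidal lesions make fractional
  isocontours cleaner than clinical PET; the recovered best threshold shifts
  with PSF width and should not be read as a clinical recommendation.
- Sector-level scoring with a 5 mm margin saturates quickly in small glands
  (few sectors, coarse reference), which compresses the specificity range
  relative to published per-patient analyses.
- The biopsy detection model treats cores independently; real systematic
  schemes are spatially correlated with targeting.
- Inter-observer reconciliation is modelled only as independent perturbations
  with per-modality noise, and the registration quality report describes the
  synthetic outline fit, not human deformation behaviour.
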