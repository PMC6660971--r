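---
title: "Reproducibility-screened radiomics for small lung nodules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility-screened radiomics for small lung nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiomics models for lung nodules are built from hundreds of quantitative
features extracted from CT, but many of those features are unstable under
choices that routinely differ between centres: the voxel geometry
(anisotropic native voxels vs. resampled isotropic voxels) and the number
of bins used to discretize intensity histograms. A feature that changes
when the scanner protocol changes cannot carry a portable biological
signal. `radrep` implements a screening pipeline that (i) extracts a
252-feature panel per nodule under perturbed extraction settings, (ii)
retains only features whose intraclass correlation across settings is at
least 0.7, (iii) selects status-explaining features by cross-validated
LASSO within each setting and intersects the selections into a signature,
(iv) validates the signature with a 200-tree random forest on an
independent test cohort, and (v) audits which nodules break the
neighbourhood-based texture families, turning the survivors' confidence
intervals into minimum-nodule-size guidelines.

Because clinical cohorts of segmented nodules cannot be redistributed,
the package ships a synthetic nodule generator whose cohorts possess the
statistical structure the analysis assumes. Every pipeline stage is
exercised and tested against those synthetic cohorts.

## The synthetic cohort model

`generate_case()` rasterizes one nodule onto a voxel grid:

* **Background** is lung parenchyma at −850 HU plus i.i.d. Gaussian image
  noise (default SD 20 HU, a typical low-dose chest CT noise level).
* **Core density** interpolates between solid tissue (+20 HU) and pure
  ground-glass (−600 HU) by the `ggo_fraction` parameter; those anchors
  sit inside the standard lung/mediastinal display windows.
* **Margin**: intensity transitions from core to background through a
  logistic sigmoid in the signed distance to the nodule surface. The
  `margin_width` parameter (mm) is four logistic scale lengths, so it
  spans the central ~76% of the transition; 0 gives a step edge. The
  binary mask is always the exact support (signed distance ≤ 0), so mask
  geometry and intensity blur are decoupled.
* **Texture**: Gaussian-smoothed white noise (correlation length
  `texture_scale`, default 1.5 mm) scaled to `texture_amplitude` HU and
  confined to the interior weight — a controllable signal for the
  GLCM/NGTDM/ISZM families.
* **Shapes**: spheres, volume-preserving random ellipsoids, and
  "lobulated" spheres with a low-order spherical-harmonic radial
  perturbation (amplitude ≤ 12%) that exercises the spherical
  disproportion and fractal features.

`generate_cohort()` draws per-case spacings (in-plane 0.49–0.9 mm, slice
1–2.5 mm, mirroring routine thoracic protocols), diameters from a
truncated normal (mean 11 mm, SD 3 mm, bounded to 6–19 mm; nodules are
kept below 2 cm because small nodules are where reproducibility and
computability problems live), and a planted *small-nodule*
sub-population (3–5.5 mm) that makes the neighbourhood-based texture
families fail downstream — the failure mode the audit stage studies.

The malignant class differs from the benign class by a fixed effect
profile: +80 HU core intensity (four image-noise SDs, chosen so the
intensity channel alone separates the classes at d′ ≈ 2 against the
GGO-induced within-class spread), +3 mm mean diameter, +40 HU texture
amplitude and a 0.8 mm sharper margin. These offsets define the
"well-separated classes" regime the validation stage assumes; they were
fixed from those first principles and are not tuned.

All randomness flows through `withr::with_seed` from one explicit seed
per cohort; identical configurations reproduce bit-identical volumes,
masks and truth tables. What the generator does **not** emulate: scanner
reconstruction kernels, dose, vessels/pleura attachment, or calibrated
HU statistics of real lesions. Passing tests therefore demonstrate that
the pipeline machinery behaves correctly under controlled conditions,
not that specific clinical features are reproducible in real data.

## Preprocessing

`resample_isotropic()` down-samples to 2×2×2 mm (linear interpolation
for intensities, nearest-neighbour for masks; the origin — the centre of
the first voxel — is preserved, so resampling at the native spacing is
an exact identity). Down-sampling to the coarser common grid is the
intended direction; up-sampling would manufacture interpolated texture.
Note that nearest-neighbour digitization of a small nodule at 2 mm
carries an inherent boundary quantization of a few target voxels; mask
volume is preserved to within ~7% for 8–14 mm spheres, not exactly.

`partition_roi()` splits each ROI into the inner core (iterative
6-connected erosion, stopped at the depth whose retained volume is
nearest to 2/3 of the whole; ties go to the deeper erosion), the outer
rim (complement), and the positive subset (voxels > 0 HU — 0 HU is the
CT water point, the natural threshold for "positive voxel"). When one
erosion already empties the mask the partition is flagged degenerate and
the inner ROI collapses to the voxel nearest the centroid. For small
nodules the nearest-to-2/3 rule can select depth zero, leaving an empty
rim; rim features then fail — by design, since that is exactly what
happens to small clinical nodules.

## The 252-feature panel

The roster is fixed and ordered: 60 histogram features (19 whole-ROI,
14 positive-voxel, 9 inner, 9 outer, 9 outer−inner delta), 13 shape
features (10 3D + 3 largest-axial-slice 2D), 6 sigmoid-margin features,
15 fractal features, 44 GLCM + 44 sub-sampled GLCM features (11
Haralick-style measures × whole/inner/outer/delta), 2 ISZM features, 5
NGTDM features and 63 Laplacian-of-Gaussian response statistics (9
statistics × 7 scales). Failures are first-class: a feature that cannot
be computed is recorded with a reason (`empty_roi`, `too_few_voxels`,
`degenerate_matrix`, `fit_nonconvergence`) and never raises.

Numerical conventions shared across the panel:

* all logarithms are base 2 with 0·log 0 := 0;
* histogram entropy/uniformity discretize over the fixed CT range
  [−1024, 3071] HU, so the default 4096 bins give exactly 1 HU per bin,
  while GLCM/ISZM/NGTDM discretize equal-width over the per-ROI min–max;
* histogram energy is voxel-count normalized (mean squared intensity) so
  inner/outer deltas compare densities, not region sizes;
* kurtosis is uncorrected (normal = 3);
* the NGTDM denominators carry an ε = 10⁻¹² guard, so a constant ROI has
  coarseness 10¹².

Choices worth justifying:

* **Surface area** comes from a marching-tetrahedra mesh of the
  Gaussian-smoothed (σ = 0.53 voxel) mask indicator at level 0.5. Meshing
  the raw binary indicator overestimates the area of curved surfaces by
  ~25% (staircase bias), which would push sphere sphericity to ~0.78.
  The smoothing scale was calibrated once against analytic spheres of
  6–18 mm over isotropic and anisotropic spacings: σ = 0.53 keeps
  sphericity within [0.92, 1.0] everywhere — the most accurate setting
  that never crosses the physical bound of 1. The 2D perimeter uses the
  same construction in-plane (σ = 0.6).
* **Sigmoid margin**: for surface voxels (capped at 120 per case by a
  deterministic even stride — the statistics are means/SDs over lines, so
  this is a sampling choice, not an approximation of a sum), a line is
  cast along the inward surface normal (gradient of the σ = 1 voxel
  smoothed mask), intensities are sampled every 0.5 mm over ±L mm for
  L ∈ {3, 5, 7}, and s(t) = a + b/(1+exp(−(t−c)/w)) is fitted by a damped
  Levenberg–Marquardt loop with deterministic initialization (a = line
  minimum, b = range, c = 0, w = 1 mm; ≤ 200 iterations; relative SSE
  tolerance 10⁻⁸; w clamped above 10⁻³ mm). The slope of a line is
  b/(4w), the maximum derivative of the fitted sigmoid. Lines with
  intensity range < 10⁻⁶ HU are degenerate; if more than half the lines
  fail, the family fails with `fit_nonconvergence`.
* **Sub-sampled GLCM** is computed after 2× block down-sampling
  (mean-pooled intensities, majority-pooled mask) with the pooling blocks
  anchored at the ROI bounding box, which makes the family invariant to
  translating the nodule within the grid. Grid-anchored pooling would
  change values with the parity of the nodule position.
* **Fractal features**: box counting uses dyadic box sizes {1, 2, 4, 8,
  16} clipped to the bounding box and requires a maximum bbox extent of
  at least 4 voxels, so a one-voxel-thick plate still yields its
  dimension (~2) while genuinely tiny masks fail; lacunarity is the
  gliding-box variance-to-mean-squared ratio plus one at box sizes 2–8;
  the blanket signature S(ε) of the masked intensity surface equals 2
  exactly for a flat surface — the implemented limit tests check both.
* **LoG**: σ is specified in voxels (0.5–3.5), the analytic 3D kernel is
  DC-corrected, and the volume is replicate-padded before FFT
  convolution so edge effects stay out of the mask.

## Reproducibility screening and selection

The ICC form is the two-way random-effects, absolute-agreement,
single-measurement coefficient — the two extraction settings are the
"raters", and absolute agreement (not consistency) is what
reproducibility demands: a feature that doubles under resampling should
fail even if it doubles for every case. Incomplete pairs are dropped
per feature; identical constant measurements define ICC = 1; fewer than
3 complete pairs leave the feature unscreened.

Before screening, features whose failure fraction exceeds
`max_failure_rate` (default 0.2) in a training table are excluded from
the analysis entirely. This mirrors the clinical reality that rim,
positive-voxel and neighbourhood-texture features are frequently
incomputable on sub-centimetre nodules; without the exclusion, the
complete-case requirement of the selection stage would discard most of
the cohort.

LASSO selection is an L1-penalized logistic regression (`glmnet`) with
the penalty chosen at minimum mean cross-validated deviance over 10
stratified folds built from a fixed seed; selected features are the
nonzero coefficients at `lambda.min`. The signature is the intersection
of the per-setting selections, kept in roster order. By construction
signature ⊆ each LASSO selection ⊆ the ICC pass set.

The binning experiment holds the voxel geometry at isotropic 2 mm and
sweeps the GLCM gray levels {32, 64, 128} against the default 256,
keeping histogram (4096) and ISZM (32) binning fixed at their defaults;
consequently every non-GLCM feature is bit-identical across the pair of
tables and passes with ICC = 1 — the bin-invariance of histogram extrema
is a structural fact the tests assert, while GLCM features genuinely
degrade under coarse binning.

## Validation and the failure audit

The random forest uses 200 trees, ⌊√p⌋ candidate predictors per split
and a fixed seed; malignant is the positive class. AUC is the
rank-based (trapezoidal) area under the empirical ROC with ties
averaged; accuracy/sensitivity/specificity are reported at probability
threshold 0.5 (the operating point is configurable — no claim is made
that 0.5 is optimal). Feature contributions use unscaled OOB permutation
importance.

The audit splits cases into an error group (≥ 1 failed feature of the
audited family: NGTDM or sub-sampled GLCM) and a non-error group, then
compares 26 always-available features (19 whole-ROI histogram + 7 shape)
with Welch one-tailed t-tests. Two directional policies are available:
`"auto"` follows the sign of the observed mean difference (convenient
for exploration, but the directional decision then realizes the type-I
rate of a two-sided test at twice the level), while a fixed direction —
the pre-specified hypothesis that non-error nodules are larger — gives a
calibrated 5% test; the calibration property is asserted for the fixed
direction. Size guidelines are the lower 95% CI bound of the non-error
group mean for the volume-type features, rounded down to a 10-unit grid.
No multiplicity correction is applied across the 26 tests, matching the
presentation style of exploratory failure audits; `stats::p.adjust` can
be applied downstream if desired.

## Problem sizes and determinism

The shipped experiments run on synthetic cohorts of 90 training and 60
test cases (half the scale of a typical two-cohort clinical study, with
20% planted small nodules); the audit cohort uses 60 cases with 35%
small nodules; statistical calibrations use 1000 (t-test) and 100
(LASSO recovery) Monte-Carlo repetitions at n = 200. Reruns with an
identical configuration are bit-identical end to end: cohort generation,
fold assignment and forest training all derive from explicit seeds, and
feature extraction is deterministic.

## Known limitations

* The synthetic generator's HU levels are plausible anchors, not
  calibrated to any clinical cohort; absolute feature values should not
  be compared against patient data.
* The exact composition of a 252-feature clinical panel varies between
  laboratories; the roster here satisfies the stated per-family counts
  and is configuration-driven (`feature_roster()`), so it can be
  re-pointed at a different published list.
* Whether the GLCM "delta" of a clinical implementation subtracts
  features or matrices is ambiguous in the literature; this package
  subtracts features (outer − inner per measure).
* Nearest-neighbour mask resampling carries inherent boundary
  quantization (see Preprocessing); volume-sensitive conclusions at
  coarse grids should use the native-spacing volume.
* Nodules from the same patient are treated as independent cases
  throughout; with longitudinal clinical data that assumption must be
  revisited.
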