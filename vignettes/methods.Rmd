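---
title: "Methods: radiomics and shape modeling behind pcarad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics and shape modeling behind pcarad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pcarad is a computer-aided diagnosis pipeline for prostate cancer built
around three complementary descriptions of a segmented multiparametric MR
exam — water diffusion, tissue texture, and lesion morphology — fused with
the PSA blood biomarker and fed to classical classifiers under
cross-validation. This vignette explains each model, the tunable parameters
and their defaults, the numerical choices, and what the synthetic phantom
does and does not establish about real data.

## Functional features: ADC and its CDF

Diffusion-weighted MRI attenuates the signal of freely diffusing water.
Malignant prostate tissue, with its densely packed cells, restricts
diffusion, so its apparent diffusion coefficient (ADC) is lower than in
benign tissue. From the baseline acquisition `s0` (b = 0) and an acquisition
`sn` at a higher b-value, the pipeline computes, per voxel,

    ADC(x, y, z) = ln(s0 / sn) / (bn - b0)     [mm^2/s]

at the eight nonzero b-values {100, ..., 700, 1400} s/mm^2. Voxels where
either signal is non-positive leave the logarithm undefined; they are
dropped from the map's valid mask rather than clipped, so the exclusion is
auditable downstream.

Whole-prostate ADC distributions vary in size across patients, so each map
is summarised by its empirical CDF on a fixed grid: the dataset-wide ADC
minimum and maximum are estimated once (`estimate_global_range()`, persisted
as JSON so a range learned on training data can be applied to new cases),
the interval is split into 100 steps, and the CDF is evaluated at each step.
Values above the range clamp into the top step, making the final entry 1 by
construction. A degenerate range (a single ADC value in the whole cohort) is
widened by ±1e-6 mm^2/s to keep the grid defined.

The functional feature vector has 122 entries by default: each of the eight
100-step CDFs sampled at 15 equally spaced grid indices (120), plus the
case-level ADC minimum and maximum. The composition is a `functional_layout()`
object, so alternative summaries of the same CDFs are one-line changes.

## Texture features

Texture is computed on the whole prostate of the T2-weighted volume after
min–max normalization of the in-mask intensities to integer levels 0..255
(floor after scaling; a constant region maps to level 0).

* **First order (36):** mean, median, population variance and SD, excess
  kurtosis, skewness, Shannon entropy of the 256-level histogram; the
  empirical CDF at 10 equally spaced thresholds; percentiles 10–100 by 10;
  the observation count, bin count (4), bin width (64) and lower limit of a
  4-bin histogram; the four bin counts; and a duplicated descriptive mean.
  Skewness and kurtosis of a constant region are defined as 0 so every
  feature is finite on any nonempty mask.
* **GLCM (6):** one co-occurrence matrix accumulated over all 26
  unit-distance neighbour offsets in 3D (8 in-plane directions at angles
  0, π/4, π/2, 3π/4 plus the 9 upper- and 9 lower-layer offsets), counting
  only pairs with both voxels in-mask, then normalized to sum one. Because
  every offset's opposite is included, the matrix is symmetric. Features:
  contrast, correlation, angular second moment, dissimilarity, homogeneity,
  energy. When a marginal variance is zero (constant region) the correlation
  is reported as 1 — a constant image is perfectly predictable — instead of
  NaN, which would poison feature selection.
* **GLRLM (16):** maximal equal-level runs along X within each (y, z) line
  and along Z within each (x, y) column, with mask gaps breaking runs,
  accumulated into one 256 × Lmax matrix. The 16 standard run-length
  statistics follow. Gray-level-weighted features (e.g. low-gray-level run
  emphasis) use levels shifted to 1..256 so the `1/i^2` weights stay finite
  at level 0; run percentage divides the run count by the in-mask voxel
  count times the number of orientation families (2).

Both matrix builders are verified against brute-force scalar scanners on
exhaustive small volumes in the test suite.

## Shape features: spherical-harmonics reconstruction errors

The shape hypothesis is that malignant lesions grow irregular, complex
surfaces while benign lesions stay smooth. The pipeline quantifies this by
how quickly a spherical-harmonics (SH) expansion of the lesion surface
converges:

1. **Meshing.** The lesion mask is smoothed with a small Gaussian
   (σ = 0.6 voxels) and the 0.5-isosurface is extracted by marching
   tetrahedra, yielding a closed, watertight, genus-0 triangulation. σ was
   chosen so that digitized ball and ellipsoid phantom surfaces reproduce
   their analytic areas to about ±2%: heavier smoothing systematically
   shrinks high-curvature regions, lighter smoothing inherits the voxel
   staircase (which inflates area). For lesions so small that smoothing
   pushes the whole field under the iso level (e.g. a single voxel), the
   binary field is meshed directly. Meshes above the decimation target are
   re-extracted on a trilinearly resampled coarser grid — unlike
   edge-collapse decimation this cannot open holes or change genus.
2. **Origin.** The centroid of the lesion voxels, verified to lie strictly
   inside the surface by ray casting; for non-star-shaped regions (e.g. a
   crescent) the deepest interior voxel by erosion depth is used instead.
3. **Spherical parameterization.** Vertices are radially projected onto the
   unit sphere and relaxed by attraction–repulsion cycles: each node moves
   toward its mesh neighbours (difference vectors weighted by
   `||d||^2 + C_A2`, scaled by `C_A1`), away from all other nodes (inverse
   distance, scaled by `C_R / (2I)`), and is re-projected to unit norm.
   Iteration stops when the mean per-node displacement falls below 1e-4 or
   after 500 cycles. Defaults `C_A1 = 0.1`, `C_A2 = 0.2`, `C_R = 0.5`: with
   `C_A1` much above 0.2 the update overshoots on fine meshes (~2000
   vertices) and the system oscillates without converging, so the package
   default sits well inside the stable region; on failure the relaxation is
   automatically restarted with the attraction halved. Isolated sliver
   folds that survive convergence on coarse meshes are removed by local
   Laplacian untangling (affected nodes moved to the normalized mean of
   their neighbours); the final map is then required to be fold-free — any
   remaining flipped spherical triangle is an error, because a folded map
   breaks the one-to-one correspondence the SH expansion needs.
4. **SH expansion.** The radius of each vertex from the origin is a function
   on the sphere, `r(θ, φ)`, fitted in the real orthonormal SH basis up to
   degree 85. The basis is built with the stable normalized
   associated-Legendre recursions (no factorials, so degree 85 stays finite).
   Degree blocks are orthogonalized sequentially (block Gram–Schmidt QR
   with re-orthogonalization), which makes marker k — the RMS radial
   residual of the least-squares fit of orders 0..k — exact for every k and
   non-increasing by construction. Once the design saturates (more basis
   columns than vertices), numerically dependent columns are dropped with
   coefficient zero; this rank-revealing treatment replaces a ridge solve,
   which at degree 85 would require forming a 7396 × 7396 normal matrix per
   lesion for no gain in the markers.

The 85 markers are these per-order reconstruction errors. Reading shape
complexity from error decay rather than from raw coefficients makes the
markers nearly invariant to pose: rotating a mask by 90° changes each
marker by under 5% in the tests. Markers scale linearly with lesion size;
`normalize = TRUE` divides by the mean radius for scale invariance when
size should not inform the classifier.

## Feature fusion and stepwise selection

The fused table concatenates functional (122), texture (58), shape (85) and
PSA (1) into 266 named columns. Bi-directional stepwise selection then
operates on a logistic regression of the binary diagnosis: forward steps add
the candidate with the smallest likelihood-ratio entry p-value when it
passes the significance threshold; backward steps remove any included
feature whose removal p-value exceeds it. The two study thresholds are 0.05
and 0.1. The model behind the p-values is a design choice — the selection
literature leaves it open for binary outcomes — and logistic regression
keeps the thresholds interpretable as type-I error rates of the entry test;
on pure-noise tables the mean selected-set size tracks `threshold × p`, which
the acceptance suite verifies. Candidates are z-scored internally; ties
break toward the lowest column index so a selection replays exactly.
Quasi-separated fits are flagged in the trace but remain usable because the
deviance still converges.

By default, selection runs once on the full table and the chosen subset is
reused across all cross-validation schemas, mirroring a fixed published
feature set. This leaks label information into the subset; the leakage-safe
variant (`strict_selection` in `cross_validate()`) repeats the selection
inside every training fold and is the right choice when estimating honest
generalization error.

## Classifiers and evaluation

Four families with small grids: SVM (linear / gaussian / degree-2
polynomial kernels, cost {0.1, 1, 10}, gaussian width {1/p, 0.1, 1}),
random forest (30 trees), a Gini decision tree pruned to at most {1, 4, 10}
splits, and LDA (full or diagonal pooled covariance; the diagonal variant
is implemented in-package as class means with pooled per-feature
variances). Hyperparameters are chosen by inner 5-fold accuracy on the
training folds only; ties go to the first declared lattice point.

Evaluation uses stratified 5-fold, 10-fold, or leave-one-out
cross-validation, re-randomized over 10 repeats (the LOO partition is
fixed, so deterministic learners have zero variance across repeats — their
SD is reported as 0). Standardization is fit on training folds only.
Held-out predictions are pooled into confusion counts per repeat — pooling
keeps metrics defined even if a fold happens to contain one class — and
summarised as accuracy, sensitivity (malignant positive), specificity (all
in percent) and trapezoidal AUC from the retained decision scores, each as
mean ± SD over repeats. The ROC sweep steps tied scores simultaneously and
its AUC equals brute-force concordance counting, which the tests check.

## The synthetic phantom

Clinical DW/T2W volumes with expert segmentations cannot ship with a
package, so `generate_cohort()` builds cases with the class-conditional
structure the pipeline assumes:

* **Diffusion:** mono-exponential decay `s_n = s0 exp(-b D)` plus Gaussian
  noise clipped at a floor of 1 signal unit (keeping the ADC logarithm
  defined); `D` per case from N(1.8e-3, 0.15e-3) mm^2/s for benign and
  N(0.9e-3, 0.15e-3) for malignant — the malignant mean set at half the
  benign one, on the physiology that tumors restrict water motion.
* **Texture:** T2W intensities are a Gaussian random field smoothed at a
  class-dependent correlation length (3 voxels benign, 1.2 malignant), so
  malignant prostates are rougher at the voxel scale and show higher GLCM
  contrast.
* **Shape:** the lesion is a star-shaped solid with radius
  `r0 (1 + a P(θ, φ))`, `P` a band-limited (degrees 2–6) random angular
  field and the amplitude `a` the class knob (0.08 benign, 0.35 malignant),
  directly instantiating the surface-complexity hypothesis in a form the SH
  model can resolve.
* **PSA:** log-normal per class (means 8 and 20 ng/mL), truncated below at
  4 ng/mL to match the clinical inclusion criterion of an elevated PSA.
* **Geometry:** the prostate is an ellipsoid centred in a 28 × 28 × 20
  grid; a lesion that does not fit inside it is an explicit error, not a
  silent truncation.

Where the underlying study reports only directions (malignant ADC lower,
texture rougher, shapes more complex, PSA higher), the magnitudes above are
fixed, deliberately well-separated choices. The default cohort — 80 cases,
43 benign / 37 malignant — is therefore nearly separable by design: a
leave-one-out SVM on the fused features reaches 100% accuracy, and
permuting the labels collapses the AUC to 0.5. Passing these checks shows
the pipeline transmits each class signal it is supposed to measure and
invents none; it says nothing about accuracy on clinical data, where class
distributions overlap, noise is Rician, scanners vary, and segmentations
are imperfect. The phantom also omits coil bias fields, geometric
distortion and DICOM semantics by design.

## Problem sizes and numerical conventions

Cohort-scale runs (tests, acceptance script) use the 28 × 28 × 20 grid and
decimate lesion meshes to ≤ 700 vertices, which bounds the O(I²)
relaxation and the SH fits while leaving the markers' low-order behaviour
unchanged; single-case analyses default to 2000 vertices. Fixed
conventions: θ is the polar angle from +z in [0, π], φ the azimuth from +x
in [0, 2π); gray levels are 0..255 everywhere; the positive class is
malignant; all randomness flows from a single user-supplied seed.

## Known limitations

* The SH model needs an (approximately) star-shaped lesion from its origin;
  genuinely non-star-shaped lesions fail with an explicit error rather than
  a silently distorted parameterization.
* GLCM features come from the single accumulated 26-offset matrix;
  per-angle feature reporting is out of scope.
* Rician noise, bias fields and multi-scanner harmonization are not
  modelled; IVIM bi-exponential diffusion is likewise out of scope.
* Full-dataset stepwise selection is optimistic by construction — use the
  strict in-fold mode for honest error estimates.
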