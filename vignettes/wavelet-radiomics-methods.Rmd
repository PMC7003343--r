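---
title: "Wavelet-transformed 3D radiomics for treatment-response prediction: methods and design"
author: "waveRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet radiomics methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

waveRadiomics implements an end-to-end radiomic analysis of 3D
contrast-enhanced MRI lesion volumes for predicting pathological complete
response (pCR) to neoadjuvant chemotherapy in locally advanced breast
cancer. The design under study is a cohort of 55 patients (17 pCR, 38
non-pCR) in which three feature groups are extracted per segmented lesion:

1. **Volumetric textures (88)** in the full lesion VOI: 11 shape, 25
   first-order histogram, 22 gray-level co-occurrence (GLCM), 16
   run-length (GLRLM) and 14 zone-size (GLZSM) features.
2. **Peripheral textures (77)** — the same catalog minus shape — in a
   10 mm band centred on the lesion boundary (5 mm inner + 5 mm outer).
3. **Wavelet textures (616 = 8 x 77)** — the non-shape catalog computed in
   the lesion mask on each of the eight subbands (LLL ... HHH) of a
   single-stage 3D wavelet decomposition.

Six random-forest models are built from the group combinations
(I: volumetric; II: volumetric+peripheral; III: wavelet; IV:
volumetric+wavelet; V: peripheral+wavelet; VI: all three), each with
two-round feature selection (Boruta-style screening, then iterative
leave-one-feature-out AUC culling), SMOTE balancing to 50+50 samples, and
repeated stratified 10-fold cross-validation (100 trees, node size 1,
`ceiling(sqrt(p))` candidate features per split).

Because the study's imaging data are not publicly deposited, the package
ships a synthetic-cohort generator that reproduces the statistical
structure the analysis relies on, so every stage is testable end to end.

## Texture definitions and numerical choices

**Quantization.** All matrix textures operate on gray levels obtained by
equal-width binning of the in-mask intensities between the in-mask
minimum and maximum (`nLevels = 32` by default; a fixed bin *count*, the
common radiomics default). The study software's discretization is not
specified; fixed-count min–max binning has the advantage that adding a
constant to the image leaves every matrix feature unchanged, a property
frozen in the test suite. A constant region maps wholly to level 1.

**Directions.** Co-occurrence and run-length statistics use the 13 unique
3D offsets at voxel distance 1; features are computed per direction and
averaged (the classical Haralick aggregation) rather than pooled into a
merged matrix. Directions with no in-mask voxel pair are skipped in the
GLCM average; a single-voxel region returns all-zero matrix features with
a warning so batch extraction stays total.

**Zones.** GLZSM zones are 26-connected components of equal gray level;
zone percentage is the number of zones over the number of in-mask voxels.

**Shape.** Volume is voxel count times voxel volume. Surface area uses a
mesh-free coarea estimator: the Gaussian-smoothed binary mask (sigma =
1.5 x the largest spacing, isotropic in mm) is differentiated by central
differences and the gradient magnitude integrated over the grid. On a
digital ball of radius 10 mm at 0.5 mm spacing this is within about 1% of
the analytic sphere area; the test suite asserts the 10% band together
with sphericity in [0.95, 1.05]. The maximum 3D diameter is the largest
distance between foreground voxel centres (computed on the surface
voxels), and the three axis lengths are `4*sqrt(lambda)` of the
coordinate covariance eigenvalues.

**Histogram.** Moments are population moments; skewness and kurtosis are
defined as 0 for constant regions. Entropy, uniformity and the mode bin
use the quantized histogram, so entropy is 0 and uniformity 1 exactly
when the region is constant.

## The peritumoral band

The band is defined metrically: in-lesion voxels whose Euclidean distance
to the nearest background voxel is at most 5 mm, united with background
voxels within 5 mm of the lesion, with distances computed by an exact
anisotropic distance transform (Felzenszwalb/Huttenlocher, separable
passes weighted by the physical spacing). Whether the original analysis
used Euclidean or morphological (voxel-step dilation) distances is not
stated; the Euclidean form is exact under anisotropic spacing, which
voxel-step morphology is not. Bands reaching the grid edge are truncated
with a warning. The band is quantized on its own intensity range,
independently of the VOI: each region is treated as a self-contained
texture domain.

## The stationary wavelet decomposition

The decomposition is **undecimated** (stationary): the low/high filter
pair is applied separably along X, Y and Z in all eight combinations with
half-sample symmetric boundary extension and no downsampling, so every
subband retains the input dims and spacing. This is the package's
resolution of the largest gap in the study description: subband textures
are computed "in the segmented lesion VOI", which requires subbands
aligned with the original-resolution mask — a decimated transform would
halve the dims and orphan the mask. Subband label position 1/2/3 names
the X/Y/Z filter (LLH = low-pass X and Y, high-pass Z).

The mother wavelet is not named in the study; Haar is the default (db2 is
also available). Each subband is re-quantized on its own in-mask min–max
range, since subband value ranges differ by orders of magnitude.

## Feature selection

**Round 1 (screening).** Shadow features (per-column row permutations)
are appended, a random forest with permutation importance is fitted, and
each real feature's importance Z score is compared with the best shadow.
Hits accumulate over up to 20 iterations; a binomial test at level 0.01
accepts or rejects each feature, rejected features leave the forest, and
still-tentative features are kept (conservative). Independently, any
feature with mean importance Z below `zCutoff = 0.01` is rejected — the
study's literal "Z score cutoff of less than 0.01" rule, kept
configurable because that reading (an importance-Z threshold, not a
p-value) is unusually permissive.

Because textures on smooth random fields are strongly mutually
correlated, an all-relevant screen can retain very large sets; the
screened set is therefore capped at the `maxScreened = 30` features of
highest importance before culling. This cap is a tractability bound of
this implementation (the culling loop is quadratic in the screened size),
not part of the study description.

**Round 2 (culling).** Greedy backward elimination: the repeated-CV AUC
of the current set is compared against every one-feature-removed set
(same folds for every candidate within an iteration); the best one-less
model replaces the current one only if its AUC is strictly higher, so the
accepted-model AUC trace is non-decreasing and the loop terminates within
`|screened|` iterations. Ties are broken by dropping the feature with the
lowest screening importance. The culling AUC uses the same repeated-CV
estimator as the final evaluation with a smaller depth (10 repetitions as
the function default; the pipeline uses 5).

**Protocol order and leakage.** Selection and SMOTE are performed once on
the full balanced table, before cross-validation, replicating the study's
evident order. This leaks information into the CV estimate — see the
limitations section. Screening runs per model, after SMOTE (the study
reports per-model selected lists but does not state the order).

## Class balancing and evaluation

SMOTE oversamples **both** classes to 50 (17 pCR -> 50 and 38 non-pCR ->
50): synthetic rows interpolate uniformly between a random class member
and one of its 5 nearest same-class neighbours. The original description
mentions undersampling of the majority class, but 38 -> 50 cannot be an
undersampling; oversampling both classes is the only reading consistent
with the stated "100 samples including 50 pCR and 50 nonpCR".

Evaluation is repeated stratified 10-fold CV; out-of-fold probabilities
are pooled per repetition into one AUC (Mann–Whitney rank form), and
accuracy / sensitivity / specificity are taken at probability 0.5 (the
study reports all three without stating an operating point). Models are
compared by a two-sided unpaired t-test on the repetition-level AUC
vectors (paired is available; the study does not state which was used).

## The synthetic cohort generator

The generator emulates the study conditions: 17 pCR / 38 non-pCR
subjects; maximum lesion diameter drawn per class from normal
distributions 2.9 ± 1.1 cm (pCR) and 4.3 ± 1.9 cm (non-pCR), truncated to
[0.5, 7] cm so that lesion plus band fit the default 48³ grid at 2 mm
spacing; axis-aligned ellipsoidal masks (minor axes 0.70–0.95 of the
maximum); clinical covariates (age, enhancement type, subtype, regimen)
drawn from the per-class frequencies of the study's cohort table.

The planted class signal has two components mirroring the study's
findings: the diameter difference above, and an **intratumoral texture
grain** — the lesion interior is a Gaussian random field (white noise
smoothed by an isotropic Gaussian) whose correlation length is 1.5 mm for
pCR versus 4.0 mm for non-pCR, variance-normalized so the classes differ
in frequency content but not in intensity variance. This is the signal
that wavelet detail subbands are designed to detect. The background is a
smooth parenchyma-like field plus white scanner noise; absolute intensity
levels are free parameters (the study reports none).

`effectScale` interpolates all per-class parameter pairs towards their
midpoint: 0 yields statistically identical classes (the null used by the
chance-level tests), 1 the configured difference.

**What the generator does and does not emulate.** It produces one
axis-aligned ellipsoidal lesion per subject with stationary intratumoral
texture; real lesions are irregular, multi-focal, non-stationary, and
carry acquisition artifacts. The planted spectral effect is deliberately
strong — a positive control for signal recovery, not an effect-size
calibration: under the replicated protocol (SMOTE and selection before
CV), cross-validated AUCs saturate near 1.0 for any clearly detectable
effect, so these synthetic AUCs exceed the moderate values attainable on
real patients and say nothing about clinical performance. The package's
own null analysis (effectScale = 0 giving AUC in the 0.4–0.6 band)
together with the saturated positive control brackets what the pipeline
can show: it recovers planted signal and does not invent absent signal.

## Problem sizes and determinism

Default problem sizes were chosen so a full synthetic run is a desk-scale
computation: 48³ voxel grids at 2 mm spacing, 55 subjects, screening
capped at 30 features, culling CV at 5 repetitions in the pipeline
configuration, and 20–100 evaluation repetitions. One subject's 781
features take well under a minute on one core; the full six-model
pipeline runs in minutes.

Every stochastic stage (cohort sampling, SMOTE, shadow permutations, fold
assignment, forest fitting) receives a seed derived from the single
pipeline seed by a fixed hash, and all seeded code paths restore the
caller's RNG state; re-running a pipeline with an identical configuration
reproduces byte-identical outputs.

**A note on SMOTE under the null.** Balancing before cross-validation
leaks in a second, less obvious way: the two classes receive different
fractions of synthetic rows (17 -> 50 versus 38 -> 50), and interpolated
points have a distinctive low-dimensional geometry, so a forest can
partially separate the classes even when the images carry no class signal
at all (we measure null AUCs near 0.87 on the balanced table, versus
0.47–0.57 cross-validating the raw 17/38 table). The package's
chance-level checks therefore cross-validate the unbalanced table; the
balanced protocol is used, as in the study, only for the reported models.

## Known limitations

* The selection-before-CV protocol is replicated faithfully and is
  optimistically biased; nothing in the reported CV metrics corrects for
  the SMOTE or selection leakage.
* The surface-area estimator is smooth-surface biased: for masks a few
  voxels across it underestimates area (the test suite pins its accuracy
  only at ball scale).
* The literal Z < 0.01 rejection rule is extremely permissive on its own;
  dimensionality reduction in practice comes from the shadow comparison
  and the screened-size cap.
* Degenerate regions (single voxel, no co-occurring pair) return zero
  matrix features by convention rather than failing; downstream models
  see them as uninformative constants.
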