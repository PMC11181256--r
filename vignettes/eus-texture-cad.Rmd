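---
title: "Texture-based CAD of gastric mesenchymal tumors: methods and design notes"
author: "eustex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based CAD of gastric mesenchymal tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eustex)
```

## The problem

Gastric mesenchymal tumors seen on endoscopic ultrasonography (EUS) split
into gastrointestinal stromal tumors (GISTs), which are potentially
malignant, and benign lesions (leiomyomas, schwannomas) that look very
similar: hypoechoic masses arising from the muscularis propria. Visual
diagnosis is unreliable, so this package quantifies the lesion's *texture*
— the spatial arrangement of its gray levels — inside an expert-annotated
region of interest (ROI), and classifies lesions with a support vector
machine (SVM). GISTs are the positive class throughout.

## From image to masked pixel domain

A lesion is an 8-bit grayscale image (PNG or Windows BMP) plus a polygon ROI
stored as a JSON list of `[row, col]` vertices. Coordinates are 0-based with
the origin at the top-left pixel; rows grow downwards. Color images are
collapsed deterministically by ITU-R BT.601 luma (0.299 R + 0.587 G +
0.114 B, rounded half-up).

Rasterization uses the even-odd rule on pixel centers, with centers lying on
the polygon boundary included. This rule is deterministic, orientation- and
starting-vertex-independent, and reproducible across platforms, which is why
it is pinned rather than delegated to a geometry library with unspecified
boundary semantics. A `min_pixels` floor (default 64) rejects ROIs too small
for co-occurrence statistics to mean anything; clinical lesions (≥ 0.6 cm)
are far above it.

Two masks are derived: the ROI mask itself, and the *interior* mask — the
ROI eroded by a 3×3 box so every retained pixel has its full 8-neighborhood
inside the ROI. Pairwise (GLCM) statistics need only the mask; gradient
(GGCM) statistics are restricted to the interior so that no Sobel window
ever reads pixels outside the annotation. Computing strictly within the
mask, rather than on the ROI's bounding box, is a deliberate choice: a
bounding box would mix surrounding tissue into the texture statistics and
change every feature value.

## The three feature combinations

**GLCM48.** For each of 3 distances (d = 1, 2, 3 pixels) and 4 directions
(0°, 45°, 90°, 135°; offsets (0,+d), (−d,+d), (−d,0), (−d,−d)), the
co-occurrence matrix counts ordered in-mask pixel pairs at 256 gray levels,
and four descriptors are read off the normalized matrix p(a,b): contrast
Σ(a−b)²p, correlation Σ(a−μ_r)(b−μ_c)p/(σ_r σ_c), energy Σp², homogeneity
Σp/(1+|a−b|). That gives 3 × 4 × 4 = 48 features. Conventions worth noting:

* the matrix is *not* symmetrized — one ordered displacement per (d, θ),
  matching common library semantics; a symmetric variant is the sum of the
  matrices for ±offset, so the change is trivial if ever wanted;
* the 45°/135° sign convention above is pinned because libraries disagree;
* homogeneity uses the 1/(1+|a−b|) kernel; the 1/(1+(a−b)²) form also
  circulates, and is available via `kernel = "squared"`;
* correlation is defined as 0 when a marginal SD vanishes (constant ROI), so
  downstream classifiers always see finite features;
* gray levels default to 256 for consistency with the GGCM's gray axis;
  `levels` allows coarser, order-preserving rebinning (floor(g·L/256)).

**GLCM48_PLUS_GLOBAL3** adds three *first-order* gray statistics of the ROI:
histogram entropy (natural log, 0·log 0 ≡ 0), mean, and population SD. These
"global gray features" could alternatively be read as statistics of a pooled
co-occurrence matrix; we implement the first-order reading — the pooled-GLCM
mean/SD of the marginal reduces to almost the same quantity, and first-order
statistics are what "global gray" denotes in the texture literature.

**GGCM15.** The gray-gradient co-occurrence matrix H(i, j) counts interior
pixels with gray value i (0–255, unquantized) and quantized gradient
magnitude j (0–31). Gradients come from the standard 3×3 Sobel kernels;
magnitudes are scaled per lesion by their maximum, q = floor(m·32/gmax)
clipped to 31, with an all-flat field mapping to level 0. Per-lesion max
scaling (rather than a fixed ceiling) removes dependence on absolute echo
gain — the very reason gradient features are attractive for
non-brightness-standardized ultrasound. Fifteen classical descriptors are
computed (see `?ggcm_features` for the formulas). The classical GGCM set
has fifteen members; one of them, **gradient entropy**, is easy to omit
when listing the set from memory, and we include it explicitly as feature
12 — the remaining fourteen match the conventional names. Indices are
0-based, and small-gradient dominance divides by (j+1)² so the j = 0 column
is well defined.

All entropies in the package are in nats, consistently.

## Classification

`loocv_svm()` runs leave-one-out cross-validation: each lesion is held out
once, an SVM is trained on the remaining n − 1, and the held-out lesion's
hard label and signed decision score are recorded; with n = 120 lesions that
is 120 fits. Choices:

* **Linear kernel, C = 1.** The common "default parameters" of classical
  SVM toolboxes (including MATLAB's) are a linear kernel with unit box
  constraint; an RBF kernel is available through the `kernel` argument for
  sensitivity analysis.
* **Per-fold z-score standardization.** GGCM features span several orders
  of magnitude (gray heterogeneity is O(10³), energy is O(10⁻³)); an
  unscaled linear SVM would be dominated by a single feature.
  Standardization statistics come from the training fold only — the held-out
  lesion never influences its own fold's scaling — and the choice is
  switchable (`standardize = FALSE`). Zero-variance features are centered
  and passed with scale 1.
* **Score orientation and ties.** Scores are oriented so positive means
  GIST; an exact 0 is called negative. The procedure is deterministic given
  the table.

A caveat worth knowing: leave-one-out estimates on *exchangeable* data are
pessimistically biased. Holding out a lesion tilts the training majority
towards the other class, so under a label permutation the expected LOOCV
accuracy sits below 50% (≈ 27% at n = 10 in our simulations, drifting up
towards 50% with n). The test suite therefore checks that null accuracy
never rises *above* chance (the signature of leakage) rather than that it
equals 0.5.

## Evaluation

* `confusion_metrics()` returns sensitivity, specificity and accuracy in
  percent at full precision; display rounding is half-up to 2 decimals.
* `roc_auc()` pools the LOOCV decision scores into a single ROC per feature
  combination — the standard reading when a cross-validated score exists for
  every lesion — and computes the Mann–Whitney AUC (ties ½) with DeLong
  variance and normal-approximation 95% CI.
* `delong_paired()` compares two correlated AUCs computed on the same
  lesions via DeLong's structural components (two-sided normal p). Identical
  score vectors short-circuit to difference 0, p = 1; zero variance with
  unequal AUCs is an error rather than a silent ±Inf.
* `compare_accuracy_chi2()` is Pearson's chi-square on the 2×2
  correct/incorrect table, 1 df, *without* Yates continuity correction
  (available as a flag); equal proportions return χ² = 0, p = 1 exactly.
* `reader_table()` reproduces reader-study tables: per-reader metrics
  against fixed positives/negatives plus an unweighted mean row.
* α = 0.05, two-sided, throughout.

AUC confidence intervals here are DeLong-based; a bootstrap cross-check of
the DeLong variance (within 15% at n = 60 + 60) is part of the test suite.

## The synthetic cohort generator

`generate_cohort()` emulates what matters for texture operators in B-mode
ultrasound at desk scale — not wave physics:

1. a unit-mean multiplicative gamma speckle field (shape 1/s², dispersion
   s = `speckle_scale`);
2. Gaussian smoothing with a class-specific sigma — the *only* place the
   class enters — setting the texture correlation length;
3. renormalization to unit mean and dispersion s, so both classes have
   matched first-order statistics by construction;
4. a per-lesion multiplicative gain drawn from `gain_range`, independent of
   class, emulating non-standardized acquisition gain;
5. scaling by `base_intensity` (default 60: hypoechoic), rounding, clipping
   to 0–255, inside a randomized radial polygon ROI.

Defaults (160-px images, ROI radius 40–56 px, dispersion 0.5, smoothing
sigma 10 px for GISTs vs 1 px for non-GISTs, gain 0.75–1.25) define the
package's "well-separated" study condition and were fixed once after a
pilot Monte-Carlo. Dispersion 0.5 was chosen to keep the 8-bit dynamic
range from clipping: clipped plateaus have zero gradient and corrupt the
gradient statistics of sharp textures. Equal sigmas give an exchangeable
null cohort (AUC ≈ 0.5).

**What passing tests on this generator do and do not show.** The generator
demonstrates that the pipeline detects a pure correlation-length difference
at matched first-order statistics, that it is robust to per-lesion gain, and
that it is honest under the null. It does *not* reproduce the clinical
finding that gradient-based (GGCM) features beat gray-level (GLCM) features:
when the class signal is correlation length, the GLCM correlation descriptor
is close to a sufficient statistic and saturates at AUC 1.0 on separated
cohorts — we verified that neither gain jitter nor anisotropic smoothing
with random orientation breaks it. On such cohorts GGCM15 matches rather
than beats GLCM48 (both at AUC 1.0, GGCM occasionally a fraction below).
The clinical advantage of GGCM features presumably rests on properties of
real EUS acquisition — uncontrolled brightness/contrast transfer curves and
scanner post-processing — that this desk-scale model deliberately does not
simulate. Real-data structure the generator also omits: anisotropic,
depth-dependent speckle; boundary echoes at the lesion rim; annotation
error in the ROI polygon.

## Numerical and degenerate-input conventions

* Quantization maps are floors of exact rational scalings — no float
  comparisons on bin edges; the gradient maximum maps to the top level.
* A ROI too thin for a displacement (no valid pairs) raises an error naming
  the (d, θ) configuration; extraction over a cohort collects such failures
  per lesion and continues (`cad_extract()`).
* Empty interior masks, single-class folds, degenerate (zero-area)
  polygons, and out-of-bounds vertices are all hard errors with specific
  messages rather than NaN propagation.
* Determinism: all pipeline stages are deterministic given their inputs;
  cohort generation is a pure function of `cohort_spec()` including its
  seed. Rerunning any stage yields byte-identical CSVs.

## Problem sizes in the test suite

Oracle-equivalence tests run brute-force enumerations on images up to
24×24 (GLCM, all 12 configurations), random 256×32 count matrices (GGCM),
and exhaustive pair counting for AUC at n ≤ 8. Statistical calibration uses
2,000 null replicates at 60 + 60 for the paired DeLong test and a
10,000-rep bootstrap for the DeLong variance. Pipeline checks use cohorts
of 40–120 lesions and 20 seeded replicates for the GGCM-vs-GLCM
comparison; these sizes were chosen to keep the full suite comfortably
under a coffee break while leaving Monte-Carlo noise well below the
asserted margins.

## Known limitations

* Single still image per lesion; no multi-frame aggregation.
* No DICOM input and no interactive annotation — ROIs arrive as JSON
  polygons from elsewhere.
* The SVM is intentionally plain (no tuning, no feature selection, no
  nested CV); the package evaluates feature sets, not classifier
  engineering.
* Bootstrap CIs for single AUCs are not exposed (DeLong only), though the
  machinery exists in the tests.
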