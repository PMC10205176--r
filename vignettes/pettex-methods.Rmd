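---
title: "Methods: kinetic versus textural quantification of dynamic TSPO PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic versus textural quantification of dynamic TSPO PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pettex)
```

# Overview

`pettex` compares two ways of turning a dynamic TSPO PET acquisition into a
per-subject feature vector — region-of-interest (ROI) means of Logan DVR
parametric maps versus whole-brain 3D GLCM Haralick texture of a late summed
image — and evaluates both as inputs to a leave-one-out cross-validated
linear SVM. This vignette documents the models, the tunable parameters, the
synthetic-data generator's assumptions, and the numerical and design choices
a maintainer would want to know about.

# The kinetic branch

## Supervised cluster reference extraction

TSPO is expressed throughout the brain, so no anatomical region can serve as
a reference. The standard workaround decomposes every voxel's time-activity
curve (TAC) against a small basis of kinetic class curves and pools the
voxels that look most like "grey matter without specific binding". Our
implementation:

1. normalises each in-mask voxel TAC and each of the four class TACs to unit
   area under the curve (trapezoid on frame midpoints, with the curve pinned
   to zero at t = 0) — the decomposition should match *shape*, not
   amplitude;
2. solves a non-negative least-squares (NNLS) problem per voxel against the
   normalised basis;
3. ranks voxels by the weight of the non-binding grey-matter class and keeps
   the top `fraction` (default 0.1) of in-mask voxels, or alternatively all
   voxels above an absolute weight threshold;
4. averages the *unnormalised* TACs of the kept voxels into the reference
   TAC.

The NNLS solver enumerates active sets exactly (15 candidate sets for four
classes) and checks the Karush-Kuhn-Tucker conditions, which makes it
vectorisable across all ~10^4 voxels at once; it is verified in the test
suite against `pracma::lsqnonneg` and against an exhaustive grid-search
oracle. The `fraction = 0.1` default is a deliberately conservative choice:
it keeps only the voxels with the cleanest non-binding signature, which is
what the pseudo-reference needs; it is exposed in `pipeline_config()`.

For synthetic cohorts the class basis is taken from the generator's
ground-truth class curves. For real acquisitions a population basis must be
supplied as a CSV (one column per class, one row per frame, header = class
names, first column the non-binding grey-matter class) via
`read_kinetic_basis()`.

## Logan reference graphical analysis

For frames with midpoint at or after `t_star`, the Logan transform of a
target TAC against the reference TAC becomes linear and its slope estimates
the distribution volume ratio DVR = 1 + BP. Choices:

* **Integration.** Cumulative trapezoids on frame midpoints with the curve
  pinned to zero at t = 0, matching how frame averages discretise the
  underlying continuous curve.
* **t\* = 20 min** by default. The protocol spans 60 min and the simulated
  kinetics (k2 ≈ 0.15/min) equilibrate with a ~7–10 min time constant, so
  by 20 min the plot is linear to well under 1% while nine frames remain
  for the fit. `suggest_t_star()` implements an automatic rule (earliest
  start after which the maximum relative deviation from the final-segment
  line is below 10%) for data with unknown kinetics.
* **Failure handling.** Voxels with non-positive activity in the fit window
  or degenerate regressor variance are reported as `NaN` and counted
  (`n_failed`), never imputed.

On noiseless SRTM-simulated TACs the estimated DVR is within 0.5% of
1 + BP for BP up to 0.5 (the tests assert 5%), and is exactly
scale-invariant to a common rescaling of target and reference.

# The texture branch

The late window (default 40–60 min, exactly the last four 300 s frames of
the default protocol) is summed voxelwise; frames must lie inside the window
up to a 1 s tolerance. The summed image is quantized by linear min–max
scaling over in-mask voxels to `Ng` levels — `level = floor((x − min)/(max −
min) · Ng)` clamped to `Ng − 1` — with optional percentile clipping
(`clip_quantiles = c(0.005, 0.995)`) for outlier robustness. `Ng = 64` is
the default, a common radiomics compromise between co-occurrence sparsity
and intensity resolution at this image size; the quantization scheme is a
package choice, so absolute feature magnitudes are not comparable across
tools that bin differently.

Co-occurrences are accumulated over the 13 unique distance-1 3D directions,
pooled into a single matrix *before* normalisation, with symmetric
accumulation (the transpose added) — the classical Haralick convention.
Pairs with either voxel outside the whole-brain mask are discarded; there is
no padding. Pooling all 13 directions with symmetric accumulation covers the
full 26-neighbourhood, which makes the features exactly invariant to axis
permutations of the volume (a property the tests assert). Per-direction
features averaged across offsets are available via `per_direction = TRUE`.

All 14 classical features are computed with log base 2 and `0·log 0 ≡ 0`;
an ε = 10⁻¹² guard protects the logarithms inside the information measures
of correlation. When a marginal distribution is degenerate (a single
occupied level), correlation and the maximal correlation coefficient are
undefined and returned as `NaN` with a warning. The maximal correlation
coefficient removes zero-marginal rows/columns before forming
`Q(i,j) = Σₖ p(i,k)p(j,k)/(pₓ(i)p_y(k))` and takes the square root of the
second-largest (real part of the) eigenvalue, floored at zero. Sum variance
is centred on the sum average (rather than on sum entropy, a quirk of the
original paper tables some implementations copy); the feature remains a
variance in the strict sense.

# Selection, classification, comparison

* **Feature cap.** A 10:1 samples-per-feature rule; by default the cap is
  `floor(total_n / ratio)` — 4 features for a 19 + 21 cohort. A stricter
  per-class reading (`floor(min_class / ratio)`) is available via
  `per_class = TRUE`; the cohort-total reading is the default because it is
  the one consistent with selecting four features from 40 subjects.
* **Correlation filter.** While any pair of features has |Pearson r|
  strictly above 0.9, the member of the worst pair with the larger mean
  absolute correlation to the remaining features is dropped; exact ties
  drop the alphabetically later name. Zero-variance features are removed
  first. The procedure is deterministic.
* **Importance ranking.** One ridge-penalised logistic regression (λ = 0.01
  on standardized coefficients, intercept unpenalised) fitted by Newton
  iteration on all z-scored features jointly; importance is |coefficient|.
  The penalty keeps the fit finite on separable data, and the strictly
  convex objective makes duplicated features receive exactly equal
  coefficients, so the alphabetical tie-break is well defined. The solver
  is exact Newton rather than coordinate descent precisely so that ties are
  exact.
* **LOOCV linear SVM.** For each fold the remaining n − 1 subjects define
  the feature means and SDs (z-scoring never sees the held-out subject),
  a linear soft-margin SVM with fixed cost C = 1 is trained, and the
  held-out subject is predicted once. C = 1 is the conventional default for
  standardized features; it is exposed as `svm_cost`.
* **Metrics.** Accuracy, sensitivity, specificity (positive class = AD) and
  balanced accuracy = (sensitivity + specificity)/2; undefined ratios are
  `NaN` with a warning.
* **Cochran's Q.** Computed on the two per-subject binary response vectors.
  The default response convention is "predicted AD" — the null hypothesis
  that both classifiers call the disease label equally often — with
  "correct/incorrect" available via `response = "correct"`. Rows with
  equal responses contribute nothing; an all-concordant matrix has a zero
  denominator, for which Q ≡ 0 and p ≡ 1. For two classifiers Q equals
  McNemar's uncorrected statistic, which the tests verify exhaustively on
  all 2¹⁰ five-subject response matrices.

# Group statistics

Each feature is compared between groups with a Shapiro–Wilk gate at
α = 0.05 applied per group; both groups must pass for the two-sample t-test
(pooled variance — the plain "t-test"; Welch via `var_equal = FALSE`),
otherwise a two-tailed Mann–Whitney U test is used (exact when both groups
have n < 8 and no ties, normal approximation with tie and continuity
correction otherwise). A zero-variance group fails the gate by definition.
No multiplicity correction is applied by default, matching how such
per-feature tables are conventionally reported; Benjamini–Hochberg is
available via `adjust = "BH"`. Simulation in the test suite confirms the
composite gate-then-test procedure holds its nominal 5% type-I error at
n = (19, 21) under Gaussian nulls.

# The synthetic cohort generator

## What it emulates

* **Acquisition geometry.** A 60-min, 22-frame protocol (4 × 30 s +
  4 × 60 s + 4 × 120 s + 4 × 240 s + 6 × 300 s); frame values are
  duration-weighted averages of the underlying continuous curves.
* **Kinetics.** A bi-exponential bolus rise-and-washout reference input
  (rise 2/min, washout 0.05/min, peak 30 kBq/mL in nominal units — image
  units are arbitrary since no activity calibration is modelled), and SRTM
  responses `C_T = R1·C_ref + (k2 − R1·k2/(1+BP))·(C_ref ⊗ e^{−k2 t/(1+BP)})`
  per region. Grey matter: R1 = 1, k2 = 0.15/min; white matter: R1 = 0.35,
  k2 = 0.05/min; blood: a fast early-peaked curve (rise 8/min, washout
  0.3/min, 3× amplitude). These shapes make the four classes linearly
  distinguishable after area-normalisation, which is the supervised cluster
  method's working assumption.
* **Between-subject biology.** Each subject draws an independent
  `max(0, N(0, bp_sd))` binding potential per grey ROI (`bp_sd = 0.07`,
  giving ROI-mean DVR SDs around 0.03–0.04, the scale reported for this
  tracer), so no region is uniformly devoid of binding; disease subjects
  add `bp_ad = 0.03` in the superior frontal gyrus, reproducing a
  single-region effect of roughly 0.75 SD. Ground truth 1 + BP per voxel is
  stored in `true_dvr`.
* **Texture.** A multiplicative Gaussian random field (relative SD 0.05),
  smoothed with a Gaussian kernel whose SD is drawn per subject around the
  group correlation length (HC 1.2, AD 1.5 voxels, SD 0.25, floored at
  0.2). Being multiplicative and mean-one, it changes spatial structure
  without changing mean uptake; being spatially constant across frames, it
  perturbs voxelwise DVR only through the reference-pool averaging. The
  group difference in correlation length is what gives the texture
  classifier its signal.
* **Noise.** Zero-mean Gaussian with SD `noise_scale / sqrt(frame
  duration)` (default scale 2 kBq·mL⁻¹·s^{1/2}), the standard weighted-PET
  surrogate in which longer frames are less noisy. Data are defined
  post-decay-correction; no decay modelling.
* **Geometry.** A 32 × 32 × 16 ellipsoidal brain (configurable) with a
  central blood pool (15% of the normalised radius), a white-matter core
  (to 60%), and a grey shell split into eight octant ROIs with
  anatomical names. This size keeps a full 40-subject cohort's two-branch
  quantification under ten seconds while leaving ~6000 brain voxels for
  texture statistics.

The per-subject effect sizes were fixed once so that a 19 + 21 cohort lands
in the regime the method-comparison question is interesting in — regional
p-values of order 10⁻²–10⁻³ in the one elevated ROI, leave-one-out
accuracies in the 0.55–0.85 band across seeds — rather than at saturation,
where every classifier would be perfect and their comparison vacuous.

## What it does not emulate

No attenuation, scatter or reconstruction effects; no partial-volume
blurring of region boundaries; no head motion or registration error (all
volumes are voxel-aligned by construction); no MRI; no anatomical
variability in the region layout; Gaussian rather than Poisson-derived
noise; no arterial input function (the generator works entirely in
reference-tissue terms). Consequently, green tests demonstrate the
*pipeline's* correctness and the method comparison's behaviour under
controlled effect sizes — not that texture quantification works on real
scanner data.

# Determinism and the pipeline

`run_pipeline()` derives every random draw from the master seed
(per-subject seeds are `(seed mod 10⁶)·1000 + subject index`), so two runs
with one configuration are bit-identical, which the tests assert at full
cohort scale. Every output file carries the md5 hash of the configuration's
JSON rendering. The pipeline is exposed as R functions —
`pipeline_config()` plus `run_pipeline()`, with each stage exported
individually — rather than a shell subcommand tool, which is how analysis
packages of this kind are normally driven; `scripts/acceptance.R` is the
reproducibility entry point.

# Problem sizes used in the tests

Module tests run on 16 × 16 × 10 phantoms and cohorts of 4–12 subjects;
the oracle comparisons use 6 × 6 × 3 volumes with up to four gray levels,
where brute-force enumeration is cheap; the type-I simulation uses 400–1000
replicates; the end-to-end determinism check runs the full default
40-subject, 32 × 32 × 16 configuration twice. These sizes were chosen so
that the complete suite finishes in well under a minute while each check
still has the statistical resolution its tolerance needs.

# Known limitations

* Logan reference analysis without a k2′ correction term carries a small
  negative bias that grows with noise and with deviation from
  reference-tissue assumptions; on noiseless synthetic data it is < 0.5%.
* Absolute Haralick magnitudes depend on the (unstandardised) quantization
  scheme; only within-study group contrasts are meaningful.
* The correlation feature and the maximal correlation coefficient are
  distinct statistics here, computed independently; no equality between
  them is assumed or asserted.
* Feature selection is performed once on the full cohort before LOOCV (the
  conventional design this pipeline mirrors), so the reported accuracies
  are optimistic relative to nested selection; the comparison *between*
  the two families is unaffected since both receive the same treatment.
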