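# pettex

Kinetic and textural quantification of dynamic TSPO brain PET, compared as
classifiers.

## The problem

Dynamic PET of the 18 kDa translocator protein (TSPO) — a marker of
microglial activation imaged with tracers such as (R)-[¹¹C]PK11195 — is
classically quantified by kinetic modelling: a pseudo-reference region is
extracted by supervised cluster analysis (no brain region is truly devoid of
TSPO), voxelwise distribution volume ratios (DVR) are estimated with the
Logan reference graphical method, and parametric maps are reduced to
region-of-interest means. That route requires a full dynamic acquisition.
An alternative is to treat the spatial *texture* of a late static image as
the quantitative readout: sum a late time window, quantize the whole-brain
volume, accumulate a 3D gray-level co-occurrence matrix (GLCM) and compute
the fourteen classical Haralick features.

`pettex` implements both routes end to end and asks the question a method
comparison study asks: do texture features carry as much diagnostic
information as kinetic modelling? Each feature family is put through the
same selection stage (correlation filter at |r| > 0.9, ridge-logistic
importance ranking, a 10:1 sample-to-feature cap), a leave-one-out
cross-validated linear SVM, and per-feature group statistics with a
Shapiro–Wilk normality gate; the two classifiers are compared with
Cochran's Q on their paired binary responses.

Because patient scans cannot be redistributed, the package ships a synthetic
dynamic-PET cohort generator built on the simplified reference tissue model
(SRTM): a 60-min, 22-frame protocol, four kinetic tissue classes (grey
matter without specific binding, white matter, blood, grey matter with
specific binding), group-dependent regional binding and group-dependent
spatial texture, all reproducible from a single seed.

## The core quantities

* **Logan reference DVR.** For target and reference activity curves
  `C_T`, `C_ref`, regress `y(T) = ∫₀ᵀ C_T dt / C_T(T)` on
  `x(T) = ∫₀ᵀ C_ref dt / C_T(T)` over frames with midpoints ≥ t\*;
  the slope estimates DVR = 1 + BP.
* **Supervised cluster reference.** Each voxel TAC, normalised to unit area,
  is decomposed against four normalised class TACs by non-negative least
  squares; the voxels with the highest weight on the non-binding grey-matter
  class form the reference region.
* **Haralick features.** From the pooled, symmetric, distance-1 3D GLCM
  `p(i,j)`: energy Σp², contrast Σ(i−j)²p, correlation, variance,
  homogeneity, sum average/variance/entropy, entropy, difference
  variance/entropy, the two information measures of correlation, and the
  maximal correlation coefficient (√ of the second-largest eigenvalue of
  `Q(i,j) = Σₖ p(i,k)p(j,k) / (pₓ(i)p_y(k))`). Logs are base 2 with
  0·log 0 ≡ 0.
* **Cochran's Q.** `Q = k(k−1) Σⱼ(Gⱼ−Ḡ)² / (kΣLᵢ − ΣLᵢ²)`, df = k−1,
  chi-square upper-tail p; for two classifiers it reduces to McNemar's
  `(b−c)²/(b+c)`.

## Worked example

```r
library(pettex)

cfg <- pipeline_config(n_ad = 19, n_hc = 21, seed = 1)
res <- run_pipeline(cfg, out_dir = "demo_run")
res$comparison
#> Classifier comparison (LOOCV linear SVM)
#>         accuracy sensitivity specificity balanced_accuracy
#> kinetic    0.725      0.6842      0.7619            0.7231
#> texture    0.675      0.7895      0.5714            0.6805
#> Cochran's Q: Q = 2.0000, df = 1, p = 0.1573 (do not reject H0 at alpha = 0.05)

head(res$stats$kinetic[, c("feature", "mean_hc", "mean_ad", "test", "p_two_tailed")], 3)
#>                  feature  mean_hc  mean_ad         test p_two_tailed
#> 1 superior_frontal_gyrus 1.026313 1.061105 mann_whitney 0.0009523299
#> 2   middle_frontal_gyrus 1.020349 1.014744 mann_whitney 0.8709091431
#> 3       precentral_gyrus 1.022886 1.048040 mann_whitney 0.0544848816
```

Reading the output: both classifiers separate the groups well above chance
(accuracies ≈ 0.68–0.73 over 40 leave-one-out folds) and Cochran's Q finds
no significant difference between them — the texture route performs on par
with kinetic modelling on this cohort. The group-statistics table shows the
disease effect concentrated in the one ROI the generator elevates
(superior frontal gyrus, p ≈ 0.001), with the remaining ROIs at chance.
`demo_run/` contains the feature tables, per-subject predictions,
group-statistics TSVs and a `metrics.json` mirroring the comparison, every
file stamped with the configuration hash.

Individual stages are exported too — `generate_cohort()`,
`extract_reference_tac()`, `logan_dvr_image()`, `roi_means()`,
`texture_pipeline()`, `select_features()`, `loocv_svm()`, `cochran_q()`,
`feature_report()` — and accept NIfTI volumes with frame-timing sidecars via
`read_dynamic_pet()` for use outside the simulation.

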