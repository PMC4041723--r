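# fundusBoVW

Bag-of-visual-words (BoVW) detection of diabetic-retinopathy lesions in
colour fundus photographs, for researchers building or evaluating automated
DR screening pipelines.

Screening for diabetic retinopathy means recognising several visually
distinct lesion families — hard exudates (HE), superficial and deep
hemorrhages (SH, DH), microaneurysm-like red lesions (RL), cotton-wool
spots (CS), drusen (D) — and turning the evidence into a *referral*
decision: does this patient need an ophthalmologist within 12 months?
Instead of one ad-hoc segmentation algorithm per lesion, this package uses
a single two-tiered representation for all of them, with no vessel
segmentation or optic-disc removal:

1. **Low-level features**: 128-d upright SURF-style descriptors at sparse
   interest points (determinant-of-Hessian backend, auto-tuned to an
   average of 400 points per image inside the field-of-view mask) or on a
   dense multi-scale grid (radii 12–128 px).
2. **Mid-level BoVW**: descriptors are coded against a *class-aware*
   codebook — one k-means half learned inside specialist-annotated lesion
   regions, one half outside (2 × 250 codewords for sparse features) — and
   pooled into one vector per image. Codings: hard assignment
   (α = 1 at the nearest codeword), soft assignment / codeword uncertainty
   (Gaussian-kernel weights, `K_σ(d) = exp(−d²/2σ²)`, normalised to sum
   to 1), and **semi-soft** assignment
   (`α = 1/(d + ε)` at the nearest codeword only — codes as sparse as hard
   assignment whose influence decays slowly with distance). Pooling: sum
   (counting of words) or max; L1 normalisation by default.
3. **Classification**: one RBF-SVM per lesion with cross-validated grid
   search; a second-layer SVM over the ordered 6-tuple of calibrated
   detector scores decides referral, evaluated under 5×2-fold
   cross-validation.
4. **Evaluation**: ROC/AUC (trapezoid = tie-corrected Mann–Whitney), and a
   standardized-AUC analysis that compares treatments across lesions of
   very different difficulty by centring/scaling each lesion–dataset row.

A seeded synthetic fundus generator (circular field of view, illumination
gradient, vessel-like curvilinear structures, planted lesions with
per-label appearance priors and annotated regions, two acquisition
configurations at 640×480 and 867×575) provides a fully reproducible
test-bed emulating the cross-dataset protocol: train on configuration A,
test on configuration B.

## Worked example

```r
library(fundusBoVW)

## two acquisition configurations, 60 images each
trainSet <- generateFundusDataset(fundusConfigA(seed = 101), 60, "A")
testSet  <- generateFundusDataset(fundusConfigB(seed = 202), 60, "B")

study <- runCrossDatasetStudy(trainSet, testSet, lesions = c("HE", "RL"),
                              referral = FALSE, kHalf = 100L, seed = 1)
round(study$aucs, 1)
#>    hard-sum soft-max semisoft-max
#> HE     87.4     96.3         79.0
#> RL     93.5     98.7         98.2
```

Each entry is the cross-configuration test AUC (%) of one per-lesion
detector under one coding/pooling treatment; at this deliberately reduced
size (60 images, 100 codewords per half) the detectors are data-starved
and the treatments fluctuate. The full-size study (200 images per
configuration, 250 codewords per half, the package defaults) pushes all
three sparse treatments above 90 for both lesions — that run is what
`scripts/acceptance.R` reports (at seed 1: HE 98.9/98.9/97.5,
RL 94.1/98.8/97.4, referral 95.0 ± 2.1%).

The standardized-effect analysis of the published DR2 cross-dataset
benchmark table ships with the package:

```r
z <- standardizeAucTable(dr2BenchmarkAucs())
str(treatmentEffectSummary(z, "sparse-semisoft"))
#> List of 4
#>  $ mean  : num 1.17
#>  $ ciLow : num 0.584
#>  $ ciHigh: num 1.75
#>  $ n     : int 4
```

A mean standardized effect ≥ 1 means sparse feature extraction with
semi-soft coding sits, on average over all four lesions, one standard
deviation above the mean AUC of all treatments — the consistent-synergy
result the analysis is designed to expose.

A thin CLI over the same functions is installed under
`inst/scripts/fundusbovw` (subcommands `synth`, `extract`, `encode`,
`evaluate`, `standardize`).

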