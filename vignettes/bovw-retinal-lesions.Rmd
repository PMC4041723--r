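---
title: "Bag-of-visual-words detection of diabetic-retinopathy lesions"
author: "fundusBoVW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bag-of-visual-words detection of diabetic-retinopathy lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Diabetic retinopathy (DR) shows up in colour fundus photographs as a handful
of visually distinct lesion families: hard exudates (HE) and drusen (D) as
bright deposits, superficial and deep hemorrhages (SH, DH) and
microaneurysm-like red lesions (RL) as dark red spots and smudges, and
cotton-wool spots (CS) as fuzzy pale patches. Classical detectors are built
per lesion, with heavy pre- and post-processing. The alternative implemented
here is a single two-tiered *bag-of-visual-words* (BoVW) representation fed
to maximum-margin classifiers, one per lesion, with no vessel segmentation
or optic-disc removal anywhere in the pipeline.

The representation is the standard coding/pooling meta-model. Local
descriptors $x_j \in \mathbb{R}^{128}$, $j = 1 \dots N$, are extracted from
an image; a codebook $\{c_m\}_{m=1}^{M}$ is learned from training
descriptors; a coding function $f$ maps each descriptor to an activation
vector $\alpha \in \mathbb{R}^{M}$; a pooling function $g$ aggregates the
$N$ codes into one vector $z$, which is normalised and classified.

Three codings are provided:

* **hard** — the nearest codeword gets activation 1:
  $\alpha_m = 1$ iff $m = \arg\min_{m'} \lVert x - c_{m'}\rVert_2$;
* **soft** (codeword uncertainty) — all codewords share the activation
  through a Gaussian kernel $K_\sigma(d) = \exp(-d^2/2\sigma^2)$:
  $\alpha_m = K_\sigma(\lVert x - c_m\rVert) / \sum_{m'}
  K_\sigma(\lVert x - c_{m'}\rVert)$;
* **semi-soft** — only the nearest codeword is activated, with weight
  proportional to the inverse of its distance:
  $\alpha_m = 1/(\lVert x - c_m\rVert + \varepsilon)$ at the argmin, zero
  elsewhere. The codes are as sparse as hard assignment, but a descriptor's
  influence decays far more slowly with distance than under the Gaussian
  kernel, and the scheme needs no tuned parameter.

Pooling is either `sum` ($z_m = \sum_j \alpha_{m,j}$, the classical
counting of words) or `max` ($z_m = \max_j \alpha_{m,j}$). The standard
pairings — hard/sum, soft/max, semisoft/max — are the defaults of
`encodeImage()`. The final vector is L1-normalised by default, reading the
counting interpretation as relative frequencies; L2 and no normalisation
are available.

## Low-level features

Two extraction modes exist. **Dense**: patches on a grid with radii
12, 19, 31, 50, 80, 128 px, each radius serving as both scale and sampling
step (`sampleDense()`); the range covers small hemorrhages up to very large
structures, in a roughly geometric progression. **Sparse**: blob-like
interest points from a determinant-of-Hessian (DoH) detector
(`dohBackend()`, `detectSparse()`), the quantity SURF-family detectors
threshold. The backend is pluggable — anything producing scale-space
keypoints plus 128-d descriptors can be registered — because SURF
implementations are licensing-encumbered in several distributions; the
backend identity is recorded in all serialized artifacts.

Detector sensitivity is not set by hand: `tuneSparseBackend()` bisects the
DoH response threshold (at most 12 iterations) until the *batch mean*
keypoint count matches a target of 400 points of interest per image,
counted after field-of-view filtering. The default pyramid spans eight
scales (base 1.7, ratio 1.5): scale-space maxima are only accepted at
interior levels, so the top of the pyramid must sit above the largest
structure the detector should respond to across *both* acquisition
configurations — a pyramid trimmed to the training resolution can silently
drop the largest lesions of a higher-resolution test set. The backend's
`upsample` flag
emulates operating on twice the image resolution by shifting the scale
pyramid one octave down, which makes structures half the nominal minimum
size detectable without resampling the image.

Descriptors are upright extended SURF-style vectors: a $20\times20$ sample
grid with step $s$ over a $4\times4$ subregion layout, eight
sign-partitioned gradient statistics per subregion ($16 \times 8 = 128$),
Gaussian weighting, L2 normalisation. The sampling step is `radius / 10`,
so the descriptor window spans the patch diameter. Sparse keypoints report
`radius = 5 * sigma` of their detection scale: an early design with
`2.5 * sigma` windows captured mostly the flat interior of a blob and
discriminated lesions poorly; the wider support mirrors the generous
context window of SURF's own descriptor (roughly $\pm10\sigma$).

The field of view is segmented by thresholding the gray intensity (channel
mean scaled to $[0,1]$) at 0.08, closing with a 5-px disk brush and keeping
the largest connected component; keypoints outside the mask are discarded.
The threshold value is a package choice: it keeps the dimly lit retinal
periphery while rejecting the dark surround typical of fundus photographs.

## Class-aware codebooks

Lesion areas are small, so a codebook learned from pooled descriptors is
dominated by healthy-tissue appearance and starves the representation of
lesion codewords. `learnClassAwareCodebook()` therefore runs two
independent k-means clusterings — one on descriptors inside
specialist-annotated lesion regions, one on everything else — and
concatenates the centroid sets lesion-first into a codebook of $2k$
codewords with per-row provenance. Defaults are $k = 250$ for sparse
features and $k = 750$ for dense ones.

k-means details (Euclidean distance and a 200-round cap are the method's
standard settings; the rest are package choices): k-means++
initialisation under an explicit seed; Lloyd iterations; convergence when
the largest relative centroid shift drops below $10^{-4}$; empty clusters
reseeded to the farthest point; optional seeded subsampling of a pool
before clustering (cap 100,000 by default). Descriptors from regions of
*other* lesion types are treated as "normal" when learning a given
lesion's codebook — anything outside the target lesion's regions counts as
background for that detector.

## Detectors, grid search, and the referral decision

Each lesion gets one RBF-kernel SVM over the BoVW vectors
(`trainDetector()`), with $(C, \gamma)$ selected by stratified 5-fold
cross-validation over the usual exponential grid
($C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$, steps of $2^2$), maximising
mean fold AUC with ties broken towards the smaller values. Following the
standard libsvm grid-search recipe, features are standardised (training-set
column mean and standard deviation, stored in the model and re-applied at
scoring time) before the search: L1-normalised BoVW vectors live at
pairwise distances of order $10^{-1}$, where the whole default
$\gamma$ grid would leave the kernel essentially constant. A trained model
binds its codebook and treatment; scoring a vector encoded any other way is
an error, which is what makes the cross-dataset protocol well defined: test
images are always encoded with the training codebook and treatment.

The *referral* decision (does the patient need an ophthalmologist within
12 months?) is meta-classification: the six per-lesion detector scores, in
the fixed order HE, SH, DH, RL, CS, D, form the feature vector of a
second-layer RBF-SVM. Detector operational points are fixed on training
data only, interpreted here as per-detector score calibration — min–max to
$[0,1]$ by default, matching the "normalized probability of presence"
reading; a sigmoid squashing is available, and hard thresholding is
deliberately not used since the meta-classifier consumes continuous scores.
Evaluation uses the 5×2-fold protocol: five seeded stratified half-splits,
train on one half (calibration + grid search + SVM), test on the other,
both directions, yielding exactly 10 AUCs. The RL detector trains on the
union of the SH, DH and RL annotations, since the red-lesion label
subsumes hemorrhages and microaneurysms.

## Evaluation and the standardized-effect analysis

`rocCurve()` sweeps all distinct scores and integrates by trapezoid, which
equals the tie-corrected Mann–Whitney statistic (property-tested against an
$O(n^2)$ pair-counting oracle). Lesion–dataset combinations differ hugely
in difficulty, so treatments are compared on *standardized* AUCs:
`standardizeAucTable()` maps each row $\beta_\ell$ to
$(\beta_\ell - \mu_\ell)/\sigma_\ell$ using the row mean and sample
standard deviation over the six treatments (the sample convention is a
package choice; the headline conclusion is insensitive to it), and
`treatmentEffectSummary()` reports a column mean with a t-based 95% CI.
On the shipped DR2 cross-dataset benchmark table (`dr2BenchmarkAucs()`),
the sparse/semi-soft treatment averages more than one standard deviation
above the per-lesion mean — the consistent-synergy result the analysis is
designed to expose. The factorial ANOVA and Friedman/Nemenyi tests that
accompany that analysis in the literature are standard statistics and are
not re-implemented; the standardized table is exported for external tools.

## The synthetic fundus generator

Real DR datasets cannot be redistributed with a package, so the test-bed is
a seeded generator (`generateFundusDataset()`) that emulates the
*structure* of the problem: a circular field of view on a dark surround, a
low-frequency illumination field, an optic-disc-like bright disk,
vessel-like curvilinear random walks of decreasing width, and planted
lesions as multi-blob Gaussian-profile composites spread over their
annotated region, with label-specific priors separated along orthogonal
structural axes — polarity (bright HE/D/CS versus dark SH/DH/RL), scale
(tiny RL dots < small sharp HE < medium D < large DH/SH/CS), contrast and
sharpness (sharp exudates versus faint fuzzy cotton-wool patches), and
shape (flame-like bundles of parallel dark streaks for SH — the striated
look of superficial hemorrhages, and a texture no single vessel or round
blot shares — versus round blots for DH). The composite, spread-out
structure matters twice over: it emulates the clustered, granular look of
real lesions, and it keeps the planted instances resolvable as separate
interest points so each lesion class contributes a descriptor pool
comfortably larger than the codebook half learned from it. Lesion
contrasts are roughly equalised across classes — the determinant-of-Hessian
response grows with the square of the contrast, so a class planted much
fainter than the rest would simply fall below the tuned detection
threshold and vanish from the representation; class identity is carried by
the structural axes, which is also all the grayscale descriptors can see.
Every planted lesion is covered by
an annotated circle (2–5 regions per positive label, the typical count of
specialist markings per affected image); per-label presence is Bernoulli
with the configured mix (default 0.2 per label); referral is the OR over
planted labels. Two shipped configurations emulate the cross-dataset
protocol: "A" at 640×480 and "B" at 867×575 with brighter illumination and
slightly stronger noise — the published DR1/DR2 resolutions. Lesion and
vessel geometry scales with resolution.

Lesion contrast is set well above the pixel noise by construction, so the
planted lesions are *easily separable* — the generator validates the
machinery, not clinical difficulty. What it does not emulate: real texture
and colour statistics of the retina, vessel branching topology, lesion
co-location patterns (lesions near vessels, exudate rings), acquisition
artefacts, or severity grading. Passing the synthetic study therefore shows
that the pipeline recovers detectable structure across acquisition
configurations; it does not certify performance on real retinographs —
for that, `inst/scripts/reproduce_dr_benchmarks.R` reruns the pipeline on
the downloadable DR1/DR2/Messidor datasets.

For the soft coding scale, the canonical $\sigma = 45$ was derived for raw
SURF descriptor distances. This package's descriptors are L2-normalised,
so the study derives $\sigma$ the same way the canonical value was
obtained — from an observed population of inter-descriptor distances
(`sigmaFromDescriptors()`, a quarter of the median pairwise distance,
giving kernels that discriminate on the scale where the descriptors
actually live). The default of `codingParams()` remains 45 for backends
with raw distances.

## Problem sizes and numerical choices

The standard study (`runCrossDatasetStudy()`, also what
`scripts/acceptance.R` runs) uses 200 training and 200 test images, the
400-keypoint budget, $k = 250$ per codebook half, and caps each lesion's
normal descriptor pool at 20,000 before clustering — matching the pool
sizes reported for the original experiments (≈2,800 lesion and ≈19,700
normal descriptors), and chosen before any end-to-end run. Tie-breaks go
to the lowest codeword index everywhere. The semi-soft guard is
$\varepsilon = 10^{-12}$, so a descriptor coinciding with a codeword gets a
finite activation; the L1 normalisation that follows makes the
proportionality constant immaterial. Soft coding that underflows to an
all-zero kernel row falls back to hard assignment for that descriptor and
logs a message — which is also why the $\sigma \to 0$ limit reproduces
hard assignment exactly. All randomness (generator, k-means, fold
assignment, half-splits) flows from explicit integer seeds; repeated runs
are bit-identical.

## Known limitations

* The DoH backend is deliberately simple: no orientation assignment
  (upright descriptors), no subpixel/scale interpolation of maxima. For
  rotation-variant structures a SURF/SIFT backend can be registered
  instead.
* Dense extraction is provided and tested, but the shipped end-to-end
  study exercises the sparse mode only, where the semi-soft synergy lives.
* The synthetic generator's simplifications listed above bound what the
  green study proves about clinical data.
* Class imbalance is not reweighted by default (a `classWeights` flag
  exists on `trainDetector()`).

```{r example}
library(fundusBoVW)

## a small end-to-end run (shrink n for a quick look)
trainSet <- generateFundusDataset(fundusConfigA(seed = 101), 60, "A")
testSet  <- generateFundusDataset(fundusConfigB(seed = 202), 60, "B")
study <- runCrossDatasetStudy(trainSet, testSet, lesions = c("HE", "RL"),
                              referral = FALSE, kHalf = 100L, seed = 1)
round(study$aucs, 1)

## the standardized-effect analysis of the published DR2 benchmark
z <- standardizeAucTable(dr2BenchmarkAucs())
treatmentEffectSummary(z, "sparse-semisoft")
```
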