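---
title: "Methods: non-contrast CT radiomics signatures for renal revascularization outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-contrast CT radiomics signatures for renal revascularization outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical question and the modeling task

Severe atherosclerotic renal artery stenosis (ARAS) can be treated by
percutaneous transluminal renal angioplasty (PTRA), but only a subset of
patients shows a durable renal-function response. The outcome of interest is
binary: a patient *benefits* when the estimated glomerular filtration rate
(eGFR) rises by at least 20% over the pre-treatment level and the rise
persists for at least 3 months; a sustained fall of at least 20% is
exacerbation, anything in between is stable, and only improvement counts as
benefit. `classify_outcome()` implements this rule as a total function of
(pre-eGFR, post-eGFR, follow-up months), with inclusive thresholds at exactly
&plusmn;20%. A follow-up shorter than 3 months cannot establish persistence,
so it yields an explicit `"undetermined"` status with an `NA` label rather
than a silent non-benefit — a deliberate design choice, since conflating
"too early to tell" with "did not benefit" would contaminate training labels.

The package predicts this label before treatment from a single axial
non-contrast CT slice, using two regions of interest: the affected kidney
(ROI1) and the surrounding perirenal adipose tissue (ROI2). The premise is
that renal parenchymal texture reflects ischemic change while perirenal fat
texture reflects peri-vascular inflammation, so the two regions carry
complementary signal.

## Synthetic phantom cohorts

No patient images ship with the package; a synthetic generator stands in for
them and defines the study conditions under which every test runs.
`generate_slice()` draws a soft-tissue body ellipse (~+40 HU), an elliptical
kidney (~+32 HU) and a hypodense perirenal fat annulus (~-90 HU) on an air
background, with independent Gaussian within-tissue texture
(`kidney_texture_sd`, `fat_texture_sd`) plus global acquisition noise
(default 4 HU). These HU values are standard tissue ranges; the texture SDs
(defaults 8 and 10 HU) are the heterogeneity knobs through which effects are
planted. Texture is independent pixel noise by design: it keeps every
sampling-error bound derivable in closed form, at the price of lacking the
spatial autocorrelation of real parenchyma — a stated limit on what passing
tests show about real CT.

`build_cohort()` produces the labeled cohort, by default 52 cases split
18 benefit / 34 non-benefit. Labels must follow a logistic model in the
planted effects while the class counts stay fixed, so the generator draws
latent effect variables from equal-variance Gaussian class conditionals
(mean +&beta;/2 for benefit, -&beta;/2 otherwise): Bayes' rule then makes
P(benefit | latent) exactly logistic with slope &beta;. The latent modulates
the case's texture SD multiplicatively (`base * exp(0.25 u)`), keeping SDs
positive and the feature-to-latent map monotone, so the planted effect is
recoverable by rank statistics. Defaults are &beta; = 2.0 on perirenal fat
texture and 1.2 on renal texture, i.e. latent AUCs of about 0.92 and 0.80 —
a strong but not degenerate perirenal effect and a moderate renal one,
mirroring a study in which the perirenal signature outperforms the renal
one. eGFR trajectories are generated consistently with each label (class
means 77.8/63.8 ml/min/1.73m&sup2; from published cohort characteristics;
log-normal follow-up with median 3.7 months) and re-derived through
`classify_outcome()` as an internal consistency check.

## Standardization and the X/XL/XH triple

`preprocess_case()` aligns each image's gray-level histogram to pooled
cohort decile landmarks by a piecewise-linear map (monotone, hence
rank-preserving), resamples to 0.5 mm pixels with a separable natural cubic
spline (exact on constant and linear images; masks use nearest-neighbor to
stay binary), and builds three variants: the original X, the smoothed
XL = Gaussian(&sigma; = 1.5 px) &middot; X, and the difference XH = X - XL.
The differencing operator was an open choice; X - XL is the simplest
operator that enhances boundaries and streaks, makes X = XL + XH hold
pixelwise by construction, and gives XH zero mean under a unit-sum kernel.
All three defaults (&sigma;, spacing, decile landmarks) are exposed as
arguments.

## Handcrafted features (116)

The catalog is frozen by name and order in `feature_catalog()`:
8 mask-only shape features plus, per variant X/XL/XH, 14 histogram, 13 GLCM,
8 GLRLM and 1 fractal feature: 8 + 3&times;36 = 116. Shape depends only on
the mask, so it is computed once; the fractal dimension responds to each
variant's intensity surface, so it is computed per variant — this split is
what makes the count come out at exactly 116 and is a package-level
convention.

Numerical choices worth knowing:

* Discretization is fixed-bin-number (32 equal-width bins over the in-ROI
  range), robust to residual HU misalignment; a constant ROI maps to bin 1.
* The GLCM is symmetric, distance 1, averaged over the four 2D directions;
  degenerate conventions are 0&middot;log 0 = 0 and correlation of a
  zero-variance ROI defined as 1.
* GLRLM features are averaged per direction; `LRHGLE` is the low-run
  (short-run) high gray-level emphasis, sum of r(i,l)&middot;i&sup2;/l&sup2;
  normalized by the run count.
* The perimeter uses a marching-squares subpixel contour whose vertices are
  smoothed by a window-5 circular moving average; raw marching squares
  overestimates a disk's perimeter by about 6%, which would push the
  circularity of a disk to ~0.9 instead of ~1.
* The fractal dimension is shift-invariant differential box counting over
  box sizes 2-16; a flat surface yields exactly 2.

GLCM and GLRLM implementations are verified against brute-force pair and
run enumerators on random ragged ROIs to 1e-10.

## The self-supervised encoder and deep features (78)

A small convolutional network is trained on a pretext task that needs no
outcome labels: recognizing which of five degradations a 64&times;64
abdominal patch received — none, Gaussian blur (&sigma; 1-3 px), additive
noise (10-30 HU), elastic distortion (2-6 px) or translation (8-16 px,
reflection padding). Magnitude ranges were open choices set once: visible at
64&times;64 yet not trivially separable. Exactly one degradation applies per
patch, and an identity degradation with zero magnitude is rejected because
it would duplicate the "normal" class. Patches come from synthetic patients
split 7:1:2 with no patient crossing partitions.

The architecture is four blocks of [2&times;2 conv &rarr; 8 channels,
2&times;2 conv, batch norm, ReLU, squeeze-and-excitation attention, plus a
1&times;1-conv skip added to the block output], each followed by 2&times;2
max pooling (64 &rarr; 32 &rarr; 16 &rarr; 8 &rarr; 4), then global average
pooling to 8 nodes, dropout (0.25) and a fully connected softmax head with
5 outputs. All layers, backpropagation and the Adam optimizer are
implemented in base R inside the package; gradients are verified against
central finite differences in the test suite. Inputs are scaled by a fixed
0.01 (HU/100): the skip path is not batch-normalized, so unscaled HU
magnitudes destabilize early training. Training uses categorical
cross-entropy, initial learning rate 1e-3, batch 32, a plateau schedule
(&times;0.1 after 5 epochs without validation improvement) and early
stopping (after 10 such epochs). The L2 part of the fully connected
penalty enters the gradient; the L1 part is applied as a proximal
soft-threshold after each optimizer step, which produces exact zeros — with
an adaptive-moment optimizer a pure subgradient L1 leaves weights
oscillating at the learning-rate scale and never demonstrably sparsifies.

Deep features are read off the final block: channels are ranked by the
total absolute FC weight mass on their GAP node, the top 6 become D1..D6
(ties to the lower index), and the trunk is run fully convolutionally over
the whole slice. Each selected map is bilinearly upsampled to the image
grid and summarized over the ROI by 13 statistics (the map's ROI mean, six
histogram statistics, six GLCM statistics at 16 bins), giving
6 &times; 13 = 78 features. The counts 6 and 13 are fixed so the total
matches the published feature count; whole-slice inference (rather than
patch tiling) was the open choice adopted, documented here.

## Feature selection

Tables are z-scored per column (zero-variance columns dropped with a
warning). Screening routes each feature by per-class Shapiro-Wilk normality
at &alpha; = 0.05 to either Welch's t test or the Mann-Whitney U test,
two-sided; classes smaller than 4 go straight to Mann-Whitney, since
Shapiro-Wilk has essentially no power at n = 3. The retention gate is
strictly P &lt; 0.1 (a screening device, not an inference claim — no
multiplicity correction is applied by design); P &lt; 0.05 marks
significance. Under a permutation null the gate retains ~10% of features,
which the acceptance suite checks over 200 seeded permutations.

Retained features are grouped by consensus clustering: partitioning around
medoids on the 1 - |Spearman &rho;| distance (absolute value, so
anti-correlated redundant features cluster together), resampling features
at 50% without replacement 500 times. Each feature's consensus value is its
mean co-clustering probability with its full-data-partition peers across
resamples containing both; the subset's medoid feature maximizes it (ties
alphabetical). k starts at 2 and grows until every feature has
|&rho;| &gt; 0.6 with its subset medoid; if that never happens the
selection degrades to all singletons with a warning. Resample subsets are
kept strictly larger than k, as PAM requires.

LASSO-logistic shrinkage (glmnet) then refines the medoid set: 10 seeded
stratified folds, with the regularization strength chosen to maximize the
*pooled out-of-fold* AUC along the path — per-fold AUCs are unstable with
~5 held-out cases, and glmnet's own CV silently switches criteria at that
size. Ties prefer the strongest penalty. Features with nonzero coefficients,
ordered by |coefficient|, form the signature candidates.

## Models, LOOCV and fusion

Five families are tuned per region — ridge-logistic regression (glmnet),
RBF-SVM (e1071), random forest, k-NN and a one-hidden-layer neural network
(nnet) — by a joint grid search over nested feature prefixes and
hyperparameters (grids in `default_grids()`, ordered small-to-large
capacity for tie-breaking), scored by stratified 10-fold CV accuracy.
Every family is then evaluated by leave-one-out cross-validation; the
winner by LOOCV accuracy (ties: higher AUC, then the fixed order
LR &lt; SVM &lt; RF &lt; KNN &lt; ANN) becomes the region's signature.
Accuracy and AUC CIs are percentile bootstraps (2000 resamples) of the
correctness vector and of cases. The per-case scores a signature
contributes to fusion are its *out-of-fold* LOOCV probabilities — the refit
on all cases is kept for deploying on new data, but fusing in-sample scores
would leak each case into its own prediction. Fusion is a logistic
regression on the two score columns with Wald tests and variance inflation
factors; perfectly collinear scores make the VIF infinite and fusion is
refused outright. Every stochastic fit (SVM probability calibration, forest
bagging, network init, fold assignment, bootstraps) runs under a derived
seed, so entire studies are reproducible bit-for-bit.

On null cohorts this machinery must not invent signal: over 100 seeds the
winner-of-five LOOCV accuracy stays centered at the majority rate (34/52),
which the acceptance suite asserts within 0.05. Individual families sit
slightly *below* the majority rate on noise — they fit it — which is
pessimism, not the optimism LOOCV is meant to prevent.

## Explanation and descriptive analytics

`shapley_values()` attributes signature predictions to features with absent
features marginalized over a background set (the full training cohort — the
open choice adopted). For d &le; 10 it enumerates all 2^d coalitions and
applies the exact Shapley formula, so efficiency, dummy and symmetry hold
by construction; the kernel mode solves the KernelSHAP weighted
least-squares system over the same enumerated coalitions with the
efficiency constraint eliminated exactly, and the suite checks the two
agree to 1e-3. For a linear model with an independent background the values
reduce to &beta;&#7522;(x&#7522; - E[x&#7522;]), which is asserted to 1e-6.

Descriptive outputs are plot-ready tables: volcano points (signed
standardized mean difference against -log10 P, handcrafted vs deep flags),
average-linkage case/feature clustering on correlation distance with the
cophenetic correlation and the adjusted Rand index of the k = 2 case
partition against outcome labels (k = 2 is the documented convention), and
centered PCA projections. Correlation distance compares feature *patterns*
and is invariant to per-case level shifts — which is why the clustering
tests plant opposite expression profiles rather than offsets.

## Problem sizes and limitations

The shipped suites run at deliberately scaled sizes, chosen once as the
package's own study conditions: 96&times;96 phantoms on a 0.5 mm grid
(the resampling step becomes the identity), a 500-patch pretext corpus
from 25 synthetic patients trained for at most 30 epochs, 200 label
permutations for screen calibration, 100 replicates for LASSO recovery and
null-bias checks, and 20 seeds for the end-to-end study with 200 consensus
resamples (the function default remains 500). Known limitations: the
phantom lacks spatially correlated texture, organ anatomy and
contrast-phase effects; 2D only; the pretext corpus is synthetic rather
than real abdominal CT, so the encoder's channels should be read as a
working self-supervised feature extractor, not a reproduction of any
particular trained network; and published patient-level statistics cannot
be reproduced without the original (unavailable) images.
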