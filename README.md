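# renomics

Non-contrast CT radiomics signatures for predicting early benefit after
percutaneous transluminal renal angioplasty (PTRA) in severe atherosclerotic
renal artery stenosis (ARAS).

## The problem

After PTRA only some patients show a durable renal-function response —
defined as an eGFR increase of at least 20% over the pre-treatment level,
sustained for at least 3 months. `renomics` implements a complete, tested
pipeline that predicts this binary benefit label before treatment from a
single axial non-contrast CT slice, using two regions: the affected kidney
(ROI1) and the perirenal adipose tissue (ROI2). It is aimed at radiomics
researchers who want a reproducible, fully seeded reference implementation
of the whole chain, driven end-to-end by a synthetic CT phantom cohort
generator with planted, recoverable effects (no patient data ships with the
package).

## What the pipeline computes

1. **Standardization** — decile-landmark histogram alignment, cubic
   resampling to 0.5 mm, and the image triple X (original),
   XL = Gaussian-smoothed, XH = X − XL (detail residual).
2. **Handcrafted features (116)** — per ROI: 8 shape features plus, for each
   of X/XL/XH, 14 histogram, 13 GLCM, 8 GLRLM and 1 differential
   box-counting fractal feature (IBSI-style definitions, fixed-bin-number
   discretization).
3. **Deep features (78)** — a 4-block squeeze-and-excitation CNN trained by
   self-supervision to classify five patch degradations (normal / blur /
   noise / distortion / shift); the 6 information-dense channels of the
   final block (largest FC weight mass, named D1..D6) are upsampled to the
   image grid and summarized over the ROI by 13 statistics each. The
   network, backpropagation and Adam are implemented in base R and verified
   against finite differences.
4. **Selection** — z-scoring; univariate screening (Shapiro-Wilk-routed
   t / Mann-Whitney tests, retain P < 0.1); consensus clustering by PAM on
   1 − |Spearman ρ| with 50% feature resampling (medoid features, k grown
   until all within-subset |ρ| > 0.6); LASSO-logistic shrinkage choosing
   the strength with the best 10-fold out-of-fold AUC.
5. **Signatures** — LR, RBF-SVM, random forest, k-NN and ANN tuned by grid
   search over nested feature prefixes; winner by leave-one-out
   cross-validation accuracy; bootstrap CIs; logistic fusion of the renal
   and perirenal out-of-fold scores with Wald tests and VIFs.
6. **Explanation** — exact enumeration / KernelSHAP Shapley values,
   summary and force tables, volcano points, heatmap clustering with
   cophenetic correlation and adjusted Rand index, PCA projections,
   threshold analysis (accuracy, sensitivity, specificity, Youden, F1).

## Worked example

```r
library(renomics)

## a self-supervised encoder from 500 synthetic abdominal patches
ds      <- build_pretext_dataset(n_patients = 25, patches_per_patient = 20, seed = 7)
encoder <- train_pretext(build_encoder(seed = 7), ds, epochs = 30, seed = 7)

## an 18/34 phantom cohort with planted perirenal and renal texture effects
cohort <- build_cohort(n = 52, n_benefit = 18,
                       base_spec = phantom_spec(image_size = c(96, 96),
                                                pixel_spacing = 0.5),
                       seed = 21)

study <- run_study(cohort, encoder, consensus_resamples = 200, seed = 21)
study
#> radiomics_study
#>   majority LOOCV accuracy: 0.654
#>   renal: ANN, 4 feature(s), LOOCV accuracy 0.923, AUC 0.954
#>   perirenal: LR, 9 feature(s), LOOCV accuracy 1.000, AUC 1.000
#>   combined: AUC 1.000
```

Reading the output: 34/52 = 0.654 is the majority-class baseline any
informative signature must beat. The planted perirenal texture effect
(logistic slope 2.0 on the fat-texture latent, a latent AUC of ~0.92) is
recovered almost perfectly by the perirenal signature, and the moderate
renal effect (slope 1.2) yields an intermediate signature — the synthetic
analogue of a study where perirenal fat carries the stronger signal. The
fused model's AUC is never meaningfully below the better single signature.

Explanations for the winning signature:

```r
xz  <- zscore_table(extract_features_cohort(cohort, encoder)$perirenal)
sig <- study$perirenal$signature
f   <- function(m) renomics:::predict_prob(sig$fit, m)
sh  <- shapley_values(f, xz[, sig$spec$features], xz[, sig$spec$features])
head(summary_and_force_data(sh)$summary)
```

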