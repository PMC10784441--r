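Package: renomics
Title: Non-Contrast CT Radiomics Signatures for Renal Revascularization Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for non-contrast CT radiomics of the affected
    kidney and its perirenal adipose tissue in severe atherosclerotic renal
    artery stenosis, aimed at predicting early benefit (a sustained >= 20%
    eGFR improvement) after percutaneous transluminal renal angioplasty.
    Provides a synthetic CT phantom cohort generator with planted, recoverable
    texture effects; image standardization into original, smoothed and
    difference variants; 116 handcrafted features (shape, histogram, GLCM,
    GLRLM, fractal); a self-supervised degradation-pretext convolutional
    encoder with squeeze-and-excitation blocks yielding 78 deep features from
    information-dense maps; univariate screening, consensus clustering with
    partitioning around medoids, and LASSO feature selection; five-model
    leave-one-out cross-validated signature construction with logistic fusion;
    and exact/kernel Shapley-value model explanation with descriptive
    analytics (volcano, heatmap clustering, PCA, threshold analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    cluster,
    class,
    nnet,
    randomForest,
    e1071,
    glmnet,
    mclust,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
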