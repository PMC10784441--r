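# End-to-end study driver: standardize every case, extract 116 + 78 features
# per region, screen, consensus-cluster, LASSO-shrink, build the five-model
# signatures by LOOCV and fuse them.

#' Extract the full 194-feature table for each region of a cohort
#'
#' Standardizes every case ([preprocess_case()]: histogram alignment to the
#' pooled cohort deciles, resampling, X/XL/XH) and extracts the 116
#' handcrafted plus 78 deep features from the kidney (ROI1) and perirenal
#' adipose (ROI2) regions.
#'
#' @param cohort a [build_cohort()] result.
#' @param encoder a trained `pretext_encoder`.
#' @param target_spacing resampling target in mm (0.5).
#' @param sigma_smooth smoothing sigma in pixels (1.5).
#' @param align use pooled-decile histogram alignment (TRUE).
#' @return list with `renal` and `perirenal` matrices (cases x 194) and
#'   `labels`.
#' @export
extract_features_cohort <- function(cohort, encoder, target_spacing = 0.5,
                                    sigma_smooth = 1.5, align = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  reference <- if (align)
    reference_landmarks(lapply(cohort$cases, `[[`, "image")) else NULL
  one_region <- function(study, mask)
    c(extract_handcrafted(study, mask), extract_deep(encoder, study, mask))
  rows_r <- list(); rows_p <- list()
  for (id in names(cohort$cases)) {
    st <- preprocess_case(cohort$cases[[id]], reference = reference,
                          target_spacing = target_spacing,
                          sigma_smooth = sigma_smooth)
    rows_r[[id]] <- one_region(st, st$roi1)
    rows_p[[id]] <- one_region(st, st$roi2)
  }
  list(renal = do.call(rbind, rows_r), perirenal = do.call(rbind, rows_p),
       labels = cohort$labels)
}

#' Feature table in long format
#'
#' @param x cases x features matrix with dimnames.
#' @param region region tag added to every row.
#' @return data.frame with `case_id`, `region`, `feature`, `value`.
#' @export
feature_table_long <- function(x, region) {
  data.frame(case_id = rep(rownames(x), ncol(x)),
             region = region,
             feature = rep(colnames(x), each = nrow(x)),
             value = as.vector(x), stringsAsFactors = FALSE)
}

# Screen -> consensus medoids -> LASSO for one region table (z-scored).
select_region_features <- function(xz, labels, consensus_resamples, seed) {
  screen <- univariate_screen(xz, labels)
  retained <- screen$feature[screen$retained]
  retained <- intersect(retained, colnames(xz))
  if (length(retained) < 2) {
    # degenerate screen (e.g. null cohort): keep the two smallest-P features
    retained <- screen$feature[order(screen$p)][1:2]
  }
  cons <- choose_k_and_medoids(xz[, retained, drop = FALSE],
                               resamples = consensus_resamples, seed = seed)
  medoids <- cons$medoids
  if (length(medoids) >= 2) {
    las <- lasso_select(xz[, medoids, drop = FALSE], labels, seed = seed)
    support <- las$selected[order(-abs(las$coef_chosen))]
    if (!length(support)) support <- medoids[
      order(screen$p[match(medoids, screen$feature)])][1]
  } else {
    las <- NULL
    support <- medoids
  }
  list(screen = screen, consensus = cons, lasso = las, support = support)
}

#' Run the full radiomics study on a cohort
#'
#' Extraction, z-scoring, univariate screening (P < 0.1), consensus
#' clustering to medoid features, LASSO shrinkage, five-model signature
#' construction by LOOCV for each region, and logistic fusion of the two
#' signatures.
#'
#' @param cohort a [build_cohort()] result.
#' @param encoder a trained `pretext_encoder`.
#' @param grids hyperparameter grids ([default_grids()]).
#' @param consensus_resamples feature resamples for consensus clustering
#'   (500).
#' @param seed integer seed driving every stochastic step.
#' @param target_spacing,sigma_smooth forwarded to
#'   [extract_features_cohort()].
#' @return list of class `radiomics_study`: per-region `screen`,
#'   `consensus`, `lasso`, `signature`; `combined`; `labels`;
#'   `majority_accuracy`.
#' @export
run_study <- function(cohort, encoder, grids = default_grids(),
                      consensus_resamples = 500L, seed = 1L,
                      target_spacing = 0.5, sigma_smooth = 1.5) {
  feats <- extract_features_cohort(cohort, encoder, target_spacing,
                                   sigma_smooth)
  labels <- feats$labels
  out <- list(labels = labels,
              majority_accuracy = majority_loocv_accuracy(labels))
  sigs <- list()
  for (region in c("renal", "perirenal")) {
    x <- feats[[if (region == "renal") "renal" else "perirenal"]]
    xz <- suppressWarnings(zscore_table(x))
    sel <- select_region_features(xz, labels, consensus_resamples,
                                  seed = derive_seed(seed, match(region, c(
                                    "renal", "perirenal"))))
    sig <- build_signature(region, xz, labels, sel$support, grids = grids,
                           seed = derive_seed(seed, 20L + match(region, c(
                             "renal", "perirenal"))))
    out[[region]] <- c(sel, list(signature = sig))
    sigs[[region]] <- sig
  }
  out$combined <- combine_signatures(sigs$renal, sigs$perirenal, labels,
                                     seed = derive_seed(seed, 40L))
  structure(out, class = "radiomics_study")
}

#' @export
print.radiomics_study <- function(x, ...) {
  cat("radiomics_study\n")
  cat(sprintf("  majority LOOCV accuracy: %.3f\n", x$majority_accuracy))
  for (region in c("renal", "perirenal")) {
    s <- x[[region]]$signature
    cat(sprintf("  %s: %s, %d feature(s), LOOCV accuracy %.3f, AUC %.3f\n",
                region, s$spec$family, length(s$spec$features),
                s$cv$accuracy, s$cv$auc))
  }
  if (isTRUE(x$combined$refused)) {
    cat("  combined: fusion refused (collinear scores)\n")
  } else {
    cat(sprintf("  combined: AUC %.3f\n", x$combined$auc))
  }
  invisible(x)
}
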