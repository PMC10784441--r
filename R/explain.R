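# Shapley-value explanation of fitted signatures (exact coalition enumeration
# for small feature counts, kernel-weighted regression otherwise, both with
# absent features marginalized over a background cohort) and the descriptive
# analytics: volcano points, case heatmap clustering with cophenetic/ARI
# diagnostics, and PCA projection.

# Expected model output when only the features in `on` come from `x_case`
# and the rest are drawn from the background rows.
coalition_value <- function(predict_fn, x_case, background, on) {
  xb <- background
  if (length(on)) xb[, on] <- matrix(rep(x_case[on], each = nrow(background)),
                                     nrow(background))
  mean(predict_fn(xb))
}

#' Shapley values of a model's predictions
#'
#' Attributions with absent features marginalized over a background set
#' (marginal expectation). `mode = "exact"` enumerates all 2^d coalitions and
#' applies the Shapley formula, satisfying the efficiency, symmetry and dummy
#' axioms by construction (requires d <= 15). `mode = "kernel"` solves the
#' KernelSHAP weighted least-squares system over the enumerated non-trivial
#' coalitions with the efficiency constraint imposed exactly. `"auto"` picks
#' exact for d <= 10.
#'
#' @param predict_fn function mapping a numeric matrix (rows = cases, same
#'   columns as `cases`) to a numeric vector of model outputs.
#' @param cases numeric matrix of cases to explain.
#' @param background numeric matrix used to marginalize absent features
#'   (typically the full training cohort).
#' @param mode `"auto"`, `"exact"` or `"kernel"`.
#' @return list of class `shap_explanation`: `base` (expected output over the
#'   background), `values` (cases x features), `prediction` (per case),
#'   `importance` (mean absolute value per feature), `mode`.
#' @export
shapley_values <- function(predict_fn, cases, background,
                           mode = c("auto", "exact", "kernel")) {
  mode <- match.arg(mode)
  cases <- as.matrix(cases)
  background <- as.matrix(background)
  assert_that(nrow(background) > 0, "background set is empty")
  d <- ncol(cases)
  if (mode == "auto") mode <- if (d <= 10) "exact" else "kernel"
  if (mode == "exact") assert_that(d <= 15, "exact mode requires d <= 15")
  base <- mean(predict_fn(background))
  pred <- as.numeric(predict_fn(cases))
  n_sub <- 2^d
  subset_of <- lapply(seq_len(n_sub) - 1L, function(m)
    which(bitwAnd(m, 2^(seq_len(d) - 1)) > 0))
  values <- matrix(0, nrow(cases), d,
                   dimnames = list(rownames(cases), colnames(cases)))
  for (ci in seq_len(nrow(cases))) {
    v <- vapply(subset_of, function(on)
      coalition_value(predict_fn, cases[ci, ], background, on), numeric(1))
    if (mode == "exact") {
      for (i in seq_len(d)) {
        phi <- 0
        for (m in seq_len(n_sub) - 1L) {
          if (bitwAnd(m, 2^(i - 1)) > 0) next
          s <- length(subset_of[[m + 1L]])
          w <- factorial(s) * factorial(d - s - 1) / factorial(d)
          phi <- phi + w * (v[m + 1L + 2^(i - 1)] - v[m + 1L])
        }
        values[ci, i] <- phi
      }
    } else {
      # KernelSHAP: weighted regression on coalition indicators with the
      # efficiency constraint eliminated into the last feature.
      ms <- seq_len(n_sub - 2)                     # non-trivial coalitions
      Z <- t(vapply(ms, function(m)
        as.numeric(bitwAnd(m, 2^(seq_len(d) - 1)) > 0), numeric(d)))
      sz <- rowSums(Z)
      wk <- (d - 1) / (choose(d, sz) * sz * (d - sz))
      yv <- v[ms + 1L] - v[1L]
      vf <- v[n_sub] - v[1L]
      A <- Z[, -d, drop = FALSE] - Z[, d]
      yy <- yv - Z[, d] * vf
      fitw <- stats::lm.wfit(cbind(A), yy, wk)
      phi <- c(fitw$coefficients, vf - sum(fitw$coefficients))
      values[ci, ] <- phi
    }
  }
  structure(list(base = base, values = values, prediction = pred,
                 importance = colMeans(abs(values)), mode = mode),
            class = "shap_explanation")
}

#' Plot-ready Shapley summary and force tables
#'
#' @param expl a [shapley_values()] result.
#' @return list with `summary` (features sorted by global importance) and
#'   `force` (per case, contributions ordered by absolute size, with base
#'   value and prediction; a total below the base value means the model
#'   leans toward predicted benefit under the score orientation used here).
#' @export
summary_and_force_data <- function(expl) {
  stopifnot(inherits(expl, "shap_explanation"))
  imp <- sort(expl$importance, decreasing = TRUE)
  summary <- data.frame(feature = names(imp), importance = unname(imp),
                        rank = seq_along(imp), stringsAsFactors = FALSE)
  force <- do.call(rbind, lapply(seq_len(nrow(expl$values)), function(ci) {
    vals <- expl$values[ci, ]
    ord <- order(-abs(vals))
    data.frame(case = ci, feature = names(vals)[ord],
               contribution = unname(vals[ord]), base = expl$base,
               prediction = expl$prediction[ci], stringsAsFactors = FALSE)
  }))
  list(summary = summary, force = force)
}

#' Volcano-plot data from a screening result
#'
#' One point per feature: the effect axis is the signed standardized mean
#' difference, the y axis is -log10 P, with a handcrafted/deep family flag
#' (deep features are named `D<k>_...`) and the P = 0.05 significance line.
#'
#' @param screen a [univariate_screen()] result.
#' @return data.frame: `feature`, `effect`, `neg_log10_p`, `family`,
#'   `significant`.
#' @export
volcano_data <- function(screen) {
  data.frame(feature = screen$feature, effect = screen$smd,
             neg_log10_p = -log10(pmax(screen$p, .Machine$double.xmin)),
             family = ifelse(grepl("^D[0-9]+_", screen$feature),
                             "deep", "handcrafted"),
             significant = screen$significant, stringsAsFactors = FALSE)
}

#' Hierarchical case clustering with cophenetic and ARI diagnostics
#'
#' Average-linkage hierarchical clustering of cases (and of features) on the
#' correlation distance 1 - Pearson r over the significant features; reports
#' the cophenetic correlation between the case tree and its input distances,
#' and the adjusted Rand index between the k = 2 case partition and the
#' outcome labels.
#'
#' @param x numeric matrix (cases x significant features), >= 2 columns and
#'   >= 2 cases.
#' @param y two-level factor of outcome labels.
#' @param k cut height for the case partition (2).
#' @return list of class `cluster_report`: `case_tree`, `feature_tree`,
#'   `cophenetic`, `ari`, `partition`.
#' @export
heatmap_cluster <- function(x, y, k = 2L) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "need at least 2 cases")
  assert_that(ncol(x) >= 2, "need at least 2 significant features")
  dcase <- stats::as.dist(1 - suppressWarnings(stats::cor(t(x))))
  dcase[!is.finite(dcase)] <- 1
  case_tree <- stats::hclust(dcase, method = "average")
  dfeat <- stats::as.dist(1 - suppressWarnings(stats::cor(x)))
  dfeat[!is.finite(dfeat)] <- 1
  feature_tree <- stats::hclust(dfeat, method = "average")
  coph <- stats::cor(dcase, stats::cophenetic(case_tree))
  part <- stats::cutree(case_tree, k = k)
  ari <- mclust::adjustedRandIndex(part, as.integer(as.factor(y)))
  structure(list(case_tree = case_tree, feature_tree = feature_tree,
                 cophenetic = coph, ari = ari, partition = part),
            class = "cluster_report")
}

#' PCA projection of a feature table
#'
#' Centered PCA of the (already z-scored) table; per-case scores on the top
#' components for the benefit / non-benefit scatter.
#'
#' @param x numeric matrix (cases x features), >= 2 columns.
#' @param n_components components to return (2).
#' @return list of class `pca_result`: `scores` (cases x components),
#'   `loadings` (orthonormal columns), `explained_variance_ratio` (all
#'   components).
#' @export
pca_project <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  assert_that(ncol(x) >= 2, "need at least 2 features")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  nc <- min(n_components, ncol(pc$rotation))
  structure(list(scores = pc$x[, seq_len(nc), drop = FALSE],
                 loadings = pc$rotation[, seq_len(nc), drop = FALSE],
                 explained_variance_ratio = evr),
            class = "pca_result")
}
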