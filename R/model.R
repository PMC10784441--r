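# Candidate classifiers (LR, RBF-SVM, random forest, KNN, one-hidden-layer
# ANN), joint feature-prefix x hyperparameter tuning by stratified 10-fold CV,
# leave-one-out cross-validation with bootstrap CIs, signature construction
# (winner by LOOCV accuracy) and logistic fusion of the two region signatures.

MODEL_FAMILIES <- c("LR", "SVM", "RF", "KNN", "ANN")

#' Default hyperparameter grids
#'
#' Each grid is a data.frame ordered from smaller to larger capacity, used as
#' the tie-break direction during tuning. LR: inverse regularization C;
#' SVM-RBF: cost and a multiplier of the `1/(d * mean variance)` gamma
#' heuristic; KNN: neighbors; RF: trees and depth (Inf = unlimited); ANN:
#' hidden-layer size.
#'
#' @return Named list of data.frames.
#' @export
default_grids <- function() {
  list(LR = data.frame(C = c(0.01, 0.1, 1, 10)),
       SVM = expand.grid(C = c(0.1, 1, 10), gamma_mult = c(0.5, 1, 2)),
       KNN = data.frame(k = c(9, 7, 5, 3)),
       RF = expand.grid(depth = c(3, 5, Inf), ntree = c(100, 300)),
       ANN = data.frame(size = c(4, 8, 16)))
}

# Fit one family with given hyperparameters; returns an object whose
# predict_prob(newx) gives P(positive class). Deterministic via `seed`.
fit_model <- function(family, x, y, hp, seed = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  pos <- levels(y)[2]
  obj <- with_seed(seed, switch(family,
    LR = {
      # ridge-logistic; lambda = 1/(C n) maps C to the penalty scale
      xx <- if (ncol(x) == 1) cbind(x, .dummy = 0) else x
      list(fit = glmnet::glmnet(xx, y, family = "binomial", alpha = 0,
                                lambda = 1 / (hp$C * nrow(x))),
           pad = ncol(x) == 1)
    },
    SVM = {
      g <- hp$gamma_mult / (ncol(x) * max(mean(apply(x, 2, stats::var)), 1e-8))
      e1071::svm(x, y, kernel = "radial", cost = hp$C, gamma = g,
                 probability = TRUE)
    },
    RF = randomForest::randomForest(
      x, y, ntree = hp$ntree,
      maxnodes = if (is.finite(hp$depth)) 2^hp$depth else NULL),
    KNN = list(train = x, cl = y, k = hp$k),
    ANN = nnet::nnet(x, as.integer(y == pos), size = hp$size, decay = 1e-3,
                     maxit = 200, trace = FALSE)
  ))
  structure(list(family = family, obj = obj, pos = pos, hp = hp),
            class = "renomics_model")
}

predict_prob <- function(model, newx) {
  newx <- as.matrix(newx)
  switch(model$family,
    LR = {
      xx <- if (model$obj$pad) cbind(newx, .dummy = 0) else newx
      as.numeric(stats::predict(model$obj$fit, xx, type = "response"))
    },
    SVM = {
      pr <- attr(stats::predict(model$obj, newx, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, model$pos])
    },
    RF = as.numeric(stats::predict(model$obj, newx, type = "prob")[, model$pos]),
    KNN = {
      k <- min(model$obj$k, nrow(model$obj$train))
      pd <- class::knn(model$obj$train, newx, model$obj$cl, k = k, prob = TRUE)
      pwin <- attr(pd, "prob")
      ifelse(pd == model$pos, pwin, 1 - pwin)
    },
    ANN = as.numeric(stats::predict(model$obj, newx))
  )
}

cv_accuracy <- function(family, x, y, hp, foldid, seed) {
  correct <- logical(length(y))
  for (f in sort(unique(foldid))) {
    te <- foldid == f
    if (all(te) || !any(te)) next
    m <- fit_model(family, x[!te, , drop = FALSE], y[!te], hp,
                   seed = derive_seed(seed, f))
    p <- predict_prob(m, x[te, , drop = FALSE])
    correct[te] <- (p >= 0.5) == (y[te] == levels(as.factor(y))[2])
  }
  mean(correct)
}

#' Tune one model family over feature prefixes and hyperparameters
#'
#' Joint grid search over nested feature prefixes (features ordered by
#' descending absolute LASSO coefficient) and the family's hyperparameter
#' grid, scored by seeded stratified 10-fold CV accuracy. Ties prefer fewer
#' features, then smaller capacity (earlier grid row).
#'
#' @param family one of `"LR"`, `"SVM"`, `"RF"`, `"KNN"`, `"ANN"`.
#' @param x numeric matrix (cases x features, already z-scored).
#' @param y two-level factor (positive class = second level).
#' @param support_order character vector of candidate features in descending
#'   importance; prefixes of it form the feature subsets searched.
#' @param grid hyperparameter data.frame (default from [default_grids()]).
#' @param folds CV folds (10).
#' @param seed integer seed.
#' @return list of class `model_spec`: `family`, `features`, `hp`
#'   (one-row data.frame), `cv_accuracy`, `search` (all candidates).
#' @export
tune_model <- function(family, x, y, support_order, grid = NULL,
                       folds = 10L, seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (is.null(grid)) grid <- default_grids()[[family]]
  assert_that(nrow(grid) > 0, "hyperparameter grid is empty")
  x <- as.matrix(x)
  y <- as.factor(y)
  yb <- as.integer(y == levels(y)[2])
  foldid <- stratified_folds(yb, folds, seed)
  search <- expand.grid(prefix = seq_along(support_order),
                        row = seq_len(nrow(grid)))
  search$acc <- NA_real_
  for (s in seq_len(nrow(search))) {
    feats <- support_order[seq_len(search$prefix[s])]
    search$acc[s] <- cv_accuracy(family, x[, feats, drop = FALSE], y,
                                 as.list(grid[search$row[s], , drop = FALSE]),
                                 foldid, seed)
  }
  best <- search[order(-search$acc, search$prefix, search$row), ][1, ]
  structure(list(family = family,
                 features = support_order[seq_len(best$prefix)],
                 hp = grid[best$row, , drop = FALSE],
                 cv_accuracy = best$acc, search = search),
            class = "model_spec")
}

#' Leave-one-out cross-validation of a model specification
#'
#' Each case is predicted by a model fit on the remaining n - 1 cases.
#' Accuracy CI: percentile bootstrap (2000 resamples) of the per-case
#' correctness vector; AUC over the pooled held-out probabilities with a case
#' bootstrap CI. Folds whose training set collapses to one class are fit
#' anyway and flagged.
#'
#' @param spec a `model_spec` from [tune_model()] (or a list with `family`,
#'   `features`, `hp`).
#' @param x numeric matrix containing at least `spec$features`.
#' @param y two-level factor (positive class = second level).
#' @param n_boot bootstrap resamples (2000).
#' @param seed integer seed.
#' @return list of class `cv_result`: `prob` (held-out probabilities),
#'   `pred`, `accuracy`, `accuracy_ci`, `auc`, `auc_ci`, `confusion`,
#'   `roc` (data.frame), `flags`.
#' @export
loocv <- function(spec, x, y, n_boot = 2000L, seed = 1L) {
  x <- as.matrix(x)[, spec$features, drop = FALSE]
  y <- as.factor(y)
  n <- length(y)
  assert_that(n >= 3, "need at least 3 cases")
  pos <- levels(y)[2]
  prob <- numeric(n)
  flags <- character(0)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2)
      flags <- c(flags, sprintf("fold %d: single-class training set", i))
    m <- fit_model(spec$family, x[tr, , drop = FALSE], y[tr],
                   as.list(spec$hp), seed = derive_seed(seed, i))
    prob[i] <- predict_prob(m, x[i, , drop = FALSE])
  }
  pred <- factor(ifelse(prob >= 0.5, pos, levels(y)[1]), levels = levels(y))
  correct <- pred == y
  acc <- mean(correct)
  acc_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(derive_seed(seed, 999L), vapply(seq_len(n_boot),
      function(b) mean(correct[sample(n, replace = TRUE)]), numeric(1)))
    acc_ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }
  fa <- feature_auc(prob, y, n_boot = n_boot, seed = derive_seed(seed, 998L))
  confusion <- table(predicted = pred, actual = y)
  roc <- threshold_analysis(prob, y)
  structure(list(prob = prob, pred = pred, accuracy = acc,
                 accuracy_ci = acc_ci,
                 auc = fa$auc, auc_ci = fa$ci, confusion = confusion,
                 roc = roc, flags = flags),
            class = "cv_result")
}

#' LOOCV accuracy of the majority-class rule
#'
#' The baseline any informative signature must beat: each held-out case is
#' predicted as the majority class of the remaining cases.
#'
#' @param y two-level factor.
#' @export
majority_loocv_accuracy <- function(y) {
  y <- as.factor(y)
  n <- length(y)
  mean(vapply(seq_len(n), function(i) {
    tab <- table(y[-i])
    maj <- names(tab)[which.max(tab)]
    y[i] == maj
  }, logical(1)))
}

#' Build a region signature from the five candidate families
#'
#' Tunes every family, evaluates each tuned specification by LOOCV, and
#' declares the winner by LOOCV accuracy (ties: higher LOOCV AUC, then the
#' fixed order LR < SVM < RF < KNN < ANN). The winning model is refit on all
#' cases; the per-case signature scores kept for fusion are the out-of-fold
#' LOOCV probabilities, so no case influences its own score.
#'
#' @param region label, e.g. `"renal"` or `"perirenal"`.
#' @param x numeric matrix (cases x features, z-scored).
#' @param y two-level factor (positive class = second level).
#' @param support_order candidate features in descending importance (from
#'   [lasso_select()]).
#' @param grids named list of hyperparameter grids (default
#'   [default_grids()]).
#' @param folds tuning folds (10).
#' @param seed integer seed.
#' @return list of class `signature`: `region`, `spec` (winning
#'   `model_spec`), `fit` (refit on all cases), `scores` (out-of-fold),
#'   `cv` (winner's `cv_result`), `all_cv` (per-family accuracy/AUC table).
#' @export
build_signature <- function(region, x, y, support_order,
                            grids = default_grids(), folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  fam_order <- c(LR = 1, SVM = 2, RF = 3, KNN = 4, ANN = 5)
  specs <- list(); cvs <- list()
  for (fam in MODEL_FAMILIES) {
    specs[[fam]] <- tune_model(fam, x, y, support_order, grids[[fam]],
                               folds, seed = derive_seed(seed, fam_order[fam]))
    cvs[[fam]] <- loocv(specs[[fam]], x, y,
                        seed = derive_seed(seed, 10L + fam_order[fam]))
  }
  tab <- data.frame(family = MODEL_FAMILIES,
                    accuracy = vapply(cvs, `[[`, numeric(1), "accuracy"),
                    auc = vapply(cvs, `[[`, numeric(1), "auc"),
                    n_features = vapply(specs, function(s)
                      length(s$features), numeric(1)))
  win <- tab[order(-tab$accuracy, -tab$auc, fam_order[tab$family]), ][1, ]
  fam <- win$family
  fit <- fit_model(fam, x[, specs[[fam]]$features, drop = FALSE], y,
                   as.list(specs[[fam]]$hp), seed = derive_seed(seed, 77L))
  structure(list(region = region, spec = specs[[fam]], fit = fit,
                 scores = cvs[[fam]]$prob, cv = cvs[[fam]], all_cv = tab),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("%s signature: %s on %d feature(s); LOOCV accuracy %.3f, AUC %.3f\n",
              x$region, x$spec$family, length(x$spec$features),
              x$cv$accuracy, x$cv$auc))
  invisible(x)
}

#' Fuse two region signatures by logistic regression
#'
#' Logistic regression on the two out-of-fold score columns, with per-
#' signature Wald P values, variance inflation factors, and the combined
#' ROC/AUC with a bootstrap CI. Perfectly collinear scores make the VIF
#' infinite and the fusion is refused.
#'
#' @param sig1,sig2 `signature` objects (scores must be out-of-fold).
#' @param y two-level factor (positive class = second level).
#' @param seed integer seed for the AUC bootstrap.
#' @return list of class `combined_model`: `fit`, `p_values`, `vif`,
#'   `scores` (combined probabilities), `auc`, `auc_ci`, `refused`.
#' @export
combine_signatures <- function(sig1, sig2, y, seed = 1L) {
  s1 <- sig1$scores; s2 <- sig2$scores
  y <- as.factor(y)
  r <- stats::cor(s1, s2)
  if (!is.finite(r) || abs(r) > 1 - 1e-10) {
    return(structure(list(refused = TRUE, vif = c(Inf, Inf),
                          reason = "perfectly collinear signature scores"),
                     class = "combined_model"))
  }
  vif <- rep(1 / (1 - r^2), 2)
  names(vif) <- c(sig1$region, sig2$region)
  df <- data.frame(y = as.integer(y == levels(y)[2]), s1 = s1, s2 = s2)
  fit <- stats::glm(y ~ s1 + s2, family = stats::binomial(), data = df)
  pv <- summary(fit)$coefficients[-1, "Pr(>|z|)"]
  names(pv) <- c(sig1$region, sig2$region)
  scores <- as.numeric(stats::fitted(fit))
  fa <- feature_auc(scores, y, seed = derive_seed(seed, 55L))
  structure(list(refused = FALSE, fit = fit, p_values = pv, vif = vif,
                 scores = scores, auc = fa$auc, auc_ci = fa$ci),
            class = "combined_model")
}

#' Threshold analysis of probabilistic scores
#'
#' Accuracy, sensitivity, specificity, Youden index and F1 at thresholds 0,
#' 0.01, ..., 1; a case is called positive when its score is greater than or
#' equal to the threshold. F1 is 0 when no true positive exists.
#'
#' @param scores numeric vector in `[0, 1]`.
#' @param y two-level factor (positive class = second level).
#' @return data.frame with 101 rows: `threshold`, `accuracy`, `sensitivity`,
#'   `specificity`, `youden`, `f1`.
#' @export
threshold_analysis <- function(scores, y) {
  assert_that(all(scores >= 0 & scores <= 1), "scores must lie in [0, 1]")
  y <- as.factor(y)
  pos <- y == levels(y)[2]
  out <- lapply(seq(0, 1, 0.01), function(t) {
    call_pos <- scores >= t
    tp <- sum(call_pos & pos); fp <- sum(call_pos & !pos)
    fn <- sum(!call_pos & pos); tn <- sum(!call_pos & !pos)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    data.frame(threshold = t, accuracy = (tp + tn) / length(y),
               sensitivity = sens, specificity = spec,
               youden = sens + spec - 1,
               f1 = if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn))
  })
  do.call(rbind, out)
}
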