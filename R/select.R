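# Feature selection: z-scoring, univariate screening with normality-routed
# tests (P < 0.1 retention gate), consensus clustering of features with PAM on
# 1 - |Spearman| distances (medoid features), and LASSO-logistic shrinkage.

#' Z-score the columns of a feature table
#'
#' Zero-variance columns carry no information and are dropped with a warning.
#'
#' @param x numeric matrix (cases x features) with column names.
#' @return The scaled matrix (columns mean 0, SD 1) with attribute
#'   `dropped` naming removed columns and `zscored = TRUE`.
#' @export
zscore_table <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  drop <- !is.finite(sds) | sds == 0
  if (all(drop)) stopf("all columns are constant; nothing to z-score")
  if (any(drop))
    warning(sprintf("dropping %d zero-variance column(s): %s", sum(drop),
                    paste(utils::head(colnames(x)[drop], 5), collapse = ", ")))
  out <- scale(x[, !drop, drop = FALSE])
  attr(out, "dropped") <- colnames(x)[drop]
  attr(out, "zscored") <- TRUE
  out
}

#' Rank-based AUC of one feature with a bootstrap confidence interval
#'
#' Mann-Whitney AUC (ties counted one half) of `values` for discriminating
#' the second factor level of `labels`, with a seeded percentile bootstrap
#' over cases.
#'
#' @param values numeric vector.
#' @param labels two-level factor (positive class = second level).
#' @param n_boot bootstrap resamples for the CI (default 2000); 0 skips it.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with `auc` and `ci` (NULL when `n_boot = 0`).
#' @export
feature_auc <- function(values, labels, n_boot = 2000L, conf = 0.95,
                        seed = 1L) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2)
  pos <- labels == levels(labels)[2]
  assert_that(any(pos) && any(!pos), "both classes must be non-empty")
  auc_of <- function(v, p) {
    r <- rank(v)
    (mean(r[p]) - (sum(p) + 1) / 2) / sum(!p)
  }
  auc <- auc_of(values, pos)
  ci <- NULL
  if (n_boot > 0) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      repeat {
        i <- sample(length(values), replace = TRUE)
        if (any(pos[i]) && any(!pos[i])) break
      }
      auc_of(values[i], pos[i])
    }, numeric(1)))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  }
  list(auc = auc, ci = ci)
}

#' Univariate screening of features against the outcome
#'
#' Per feature: Shapiro-Wilk normality within each class at alpha = 0.05
#' routes to an independent two-sample t test (both classes normal) or to the
#' Mann-Whitney U test; classes smaller than 4 route directly to Mann-Whitney
#' (Shapiro-Wilk has essentially no power at n = 3). Two-sided P values
#' throughout. Features with P < 0.1 are
#' retained for downstream selection; P < 0.05 marks significance.
#'
#' @param x numeric matrix (cases x features).
#' @param labels two-level factor (positive class = second level).
#' @param alpha_normal Shapiro-Wilk routing level (0.05).
#' @param p_retain retention gate (0.1).
#' @param p_significant significance level (0.05).
#' @param auc_boot bootstrap resamples for per-feature AUC CIs (0 = skip).
#' @param seed integer seed for the AUC bootstrap.
#' @return data.frame (one row per feature): `feature`, `test`, `p`,
#'   `auc`, `auc_lo`, `auc_hi`, `smd` (standardized mean difference,
#'   positive-class minus negative over pooled SD), `retained`, `significant`.
#' @export
univariate_screen <- function(x, labels, alpha_normal = 0.05, p_retain = 0.1,
                              p_significant = 0.05, auc_boot = 0L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2)
  pos <- labels == levels(labels)[2]
  assert_that(any(pos) && any(!pos), "both classes must be non-empty")
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    a <- v[pos]; b <- v[!pos]
    normal <- function(g) {
      if (length(g) < 4 || stats::sd(g) == 0) return(FALSE)
      tryCatch(stats::shapiro.test(g)$p.value >= alpha_normal,
               error = function(e) FALSE)
    }
    use_t <- normal(a) && normal(b)
    p <- if (use_t) {
      stats::t.test(a, b)$p.value
    } else if (stats::sd(v) == 0) {
      1
    } else {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    fa <- feature_auc(v, labels, n_boot = auc_boot,
                      seed = derive_seed(seed, j))
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) / (length(v) - 2))
    data.frame(feature = colnames(x)[j],
               test = if (use_t) "t" else "mann-whitney",
               p = p, auc = fa$auc,
               auc_lo = if (is.null(fa$ci)) NA_real_ else fa$ci[1],
               auc_hi = if (is.null(fa$ci)) NA_real_ else fa$ci[2],
               smd = if (sp > 0) (mean(a) - mean(b)) / sp else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$retained <- out$p < p_retain
  out$significant <- out$p < p_significant
  out
}

spearman_abs_dist <- function(x) {
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 1
  1 - abs(rho)
}

#' Consensus clustering of features by PAM at a fixed k
#'
#' Features are clustered with partitioning around medoids on the
#' 1 - |Spearman rho| distance. The full-data PAM partition is the reference;
#' feature subsets are then resampled (rate 50%, without replacement, 500
#' times), PAM is re-run on each resample, and each feature's consensus value
#' is the mean probability of being co-clustered with its reference-subset
#' peers across the resamples containing both. The feature with the highest
#' consensus value in each subset is its medoid feature (ties broken
#' alphabetically).
#'
#' @param x numeric matrix (cases x features), >= k columns.
#' @param k number of feature subsets.
#' @param resamples number of feature resamples (500).
#' @param rate resampling fraction (0.5, without replacement).
#' @param seed integer seed.
#' @return list of class `consensus_result`: `k`, `assignment` (named),
#'   `consensus` (named), `medoids` (character, one per subset), `resamples`,
#'   `rate`.
#' @export
consensus_cluster <- function(x, k, resamples = 500L, rate = 0.5, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  assert_that(p >= k, "need at least k features")
  nm <- colnames(x)
  if (k == p) {
    # every feature its own subset and medoid; co-membership is trivial
    return(structure(list(k = k,
                          assignment = stats::setNames(seq_len(p), nm),
                          consensus = stats::setNames(rep(1, p), nm),
                          medoids = nm, resamples = resamples, rate = rate),
                     class = "consensus_result"))
  }
  D <- spearman_abs_dist(x)
  full <- cluster::pam(stats::as.dist(D), k, diss = TRUE, cluster.only = TRUE)
  assignment <- stats::setNames(full, nm)
  m_sub <- min(p, max(k + 1L, floor(rate * p)))  # PAM needs k < subset size
  co_hit <- matrix(0, p, p)
  co_n <- matrix(0, p, p)
  with_seed(derive_seed(seed, 7L), {
    for (b in seq_len(resamples)) {
      idx <- sort(sample(p, m_sub))
      cl <- cluster::pam(stats::as.dist(D[idx, idx]), k, diss = TRUE,
                         cluster.only = TRUE)
      same <- outer(cl, cl, "==") * 1
      co_hit[idx, idx] <- co_hit[idx, idx] + same
      co_n[idx, idx] <- co_n[idx, idx] + 1
    }
  })
  M <- ifelse(co_n > 0, co_hit / co_n, NA_real_)
  consensus <- vapply(seq_len(p), function(i) {
    peers <- which(assignment == assignment[i])
    peers <- setdiff(peers, i)
    peers <- peers[co_n[i, peers] > 0]
    if (!length(peers)) 1 else mean(M[i, peers])
  }, numeric(1))
  names(consensus) <- nm
  medoids <- vapply(sort(unique(assignment)), function(cl) {
    members <- nm[assignment == cl]
    best <- members[consensus[members] == max(consensus[members])]
    sort(best)[1]
  }, character(1))
  structure(list(k = k, assignment = assignment, consensus = consensus,
                 medoids = unname(medoids), resamples = resamples,
                 rate = rate),
            class = "consensus_result")
}

#' Choose the number of feature subsets and their medoid features
#'
#' Starting at k = 2 and increasing, consensus clustering is run until every
#' feature has |Spearman rho| > `rho_min` with its subset's medoid feature,
#' keeping every independent imaging phenotype while removing redundancy. If
#' the criterion is still unmet at k = p - 1, every feature becomes its own
#' singleton medoid (with a warning).
#'
#' @param x numeric matrix (cases x features), >= 2 columns.
#' @param rho_min within-subset correlation threshold (0.6).
#' @param resamples,rate,seed forwarded to [consensus_cluster()].
#' @return The accepted `consensus_result`, with `min_rho` recorded.
#' @export
choose_k_and_medoids <- function(x, rho_min = 0.6, resamples = 500L,
                                 rate = 0.5, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  assert_that(p >= 2, "need at least 2 features")
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[!is.finite(rho)] <- 0
  for (k in 2:max(2, p - 1)) {
    cr <- consensus_cluster(x, k, resamples, rate, seed)
    med_of <- cr$medoids[cr$assignment]
    rmin <- min(abs(rho[cbind(colnames(x), med_of)])[
      colnames(x) != med_of], Inf)
    if (rmin > rho_min || all(colnames(x) == med_of)) {
      cr$min_rho <- rmin
      return(cr)
    }
    if (k >= p - 1) break
  }
  warning("correlation criterion unreachable; returning all-singleton subsets")
  structure(list(k = p, assignment = stats::setNames(seq_len(p), colnames(x)),
                 consensus = stats::setNames(rep(1, p), colnames(x)),
                 medoids = colnames(x), resamples = resamples, rate = rate,
                 min_rho = 1),
            class = "consensus_result")
}

#' LASSO-logistic feature shrinkage with cross-validated AUC
#'
#' L1-penalized logistic regression over a log-spaced regularization grid;
#' the strength maximizing the mean seeded stratified 10-fold
#' cross-validation AUC is chosen, and the features with nonzero coefficients
#' at that strength are selected.
#'
#' @param x numeric matrix (cases x features), >= 2 columns.
#' @param labels two-level factor (positive class = second level).
#' @param nlambda grid size (50).
#' @param cv_folds folds (10).
#' @param seed integer seed for the fold assignment.
#' @return list of class `lasso_path`: `lambda`, `coefs` (features x
#'   lambda), `cv_auc` (pooled out-of-fold AUC per strength),
#'   `lambda_chosen`, `selected` (character), `coef_chosen` (named, nonzero
#'   only).
#' @export
lasso_select <- function(x, labels, nlambda = 50L, cv_folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  assert_that(ncol(x) >= 2, "need at least 2 features")
  labels <- as.factor(labels)
  y <- as.integer(labels == levels(labels)[2])
  foldid <- stratified_folds(y, cv_folds, seed)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        nlambda = nlambda)
  lam <- fit$lambda
  # pooled out-of-fold probabilities per strength (folds here hold ~5 cases,
  # too few for a stable per-fold AUC)
  oof <- matrix(NA_real_, length(y), length(lam))
  for (f in sort(unique(foldid))) {
    te <- foldid == f
    ff <- glmnet::glmnet(x[!te, , drop = FALSE], y[!te],
                         family = "binomial", alpha = 1, lambda = lam)
    oof[te, ] <- stats::predict(ff, x[te, , drop = FALSE], s = lam,
                                type = "response")
  }
  pos <- y == 1
  cv_auc <- apply(oof, 2, function(p) {
    r <- rank(p)
    (mean(r[pos]) - (sum(pos) + 1) / 2) / sum(!pos)
  })
  chosen <- which.max(cv_auc)              # ties: first = strongest penalty
  co <- fit$beta[, chosen]
  structure(list(lambda = lam, coefs = as.matrix(fit$beta),
                 cv_auc = cv_auc, lambda_chosen = lam[chosen],
                 selected = names(co)[co != 0],
                 coef_chosen = co[co != 0]),
            class = "lasso_path")
}

# Deterministic stratified fold assignment.
stratified_folds <- function(y, folds, seed) {
  foldid <- integer(length(y))
  with_seed(derive_seed(seed, 11L), {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      foldid[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  foldid
}
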