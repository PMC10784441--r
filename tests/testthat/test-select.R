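test_that("z-scoring normalizes, is idempotent and drops constant columns", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 0, 5))
  z <- zscore_table(x)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, stats::sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unclass(zscore_table(z))[, ], unclass(z)[, ], tolerance = 1e-12)
  expect_warning(z2 <- zscore_table(cbind(a = 1:4, b = rep(2, 4))),
                 "zero-variance")
  expect_equal(colnames(z2), "a")
  expect_error(zscore_table(cbind(a = rep(1, 4))), "constant")
})

test_that("rank AUC handles separation, ties and sign flips", {
  y <- make_labels(3, 3)
  expect_equal(feature_auc(c(0, 1, 2, 10, 11, 12), y, n_boot = 0)$auc, 1)
  expect_equal(feature_auc(rep(5, 6), y, n_boot = 0)$auc, 0.5)
  set.seed(1)
  v <- rnorm(6)
  expect_equal(feature_auc(v, y, n_boot = 0)$auc,
               1 - feature_auc(-v, y, n_boot = 0)$auc)
  ci <- feature_auc(c(0, 1, 2, 1.5, 2.5, 3), y)$ci
  expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= ci[2])
  expect_error(feature_auc(1:3, factor(rep("a", 3), levels = c("a", "b"))),
               "non-empty")
})

test_that("screening routes by normality and applies the exact Mann-Whitney P", {
  y <- make_labels(3, 3)
  x <- cbind(f = c(4, 5, 6, 1, 2, 3))   # negatives listed first
  sc <- univariate_screen(x, y)
  expect_equal(sc$test, "mann-whitney")  # n = 3 per class routes to MWU
  expect_equal(sc$p, 0.1)                # U = 0, two-sided exact
  expect_false(sc$retained)              # gate is strict: P < 0.1
  expect_false(sc$significant)

  # a feature identical to the label is overwhelmingly retained at n = 52
  y2 <- make_labels()
  x2 <- cbind(lab = as.integer(y2 == "benefit") + rnorm(52, 0, 1e-6))
  sc2 <- univariate_screen(x2, y2)
  expect_lt(sc2$p, 1e-4)
  expect_true(sc2$retained)
  expect_gt(sc2$smd, 1)
})

test_that("retention and significance flags are nested", {
  set.seed(20)
  y <- make_labels()
  x <- matrix(rnorm(52 * 30), 52, 30,
              dimnames = list(NULL, paste0("f", 1:30)))
  x[, 1] <- x[, 1] + 2 * (y == "benefit")
  sc <- univariate_screen(x, y)
  expect_true(all(sc$feature[sc$significant] %in% sc$feature[sc$retained]))
  expect_true(sc$retained[1])
})

test_that("consensus clustering recovers planted correlation blocks exactly", {
  set.seed(5)
  z1 <- rnorm(52); z2 <- rnorm(52)
  # two blocks of exact monotone (sign-flipped) copies: within-block
  # |Spearman| = 1, across-block correlation is that of independent latents
  x <- cbind(sapply(1:10, function(i) z1 * ((-1)^i)),
             sapply(1:10, function(i) z2 * ((-1)^i)))
  colnames(x) <- sprintf("f%02d", 1:20)
  cc <- consensus_cluster(x, k = 2, seed = 5)
  expect_length(unique(cc$assignment[1:10]), 1)
  expect_length(unique(cc$assignment[11:20]), 1)
  expect_true(cc$assignment[1] != cc$assignment[11])
  expect_equal(unname(cc$consensus), rep(1, 20))
  expect_length(cc$medoids, 2)
})

test_that("k = p makes every feature its own medoid with trivial consensus", {
  set.seed(6)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, letters[1:4]))
  cc <- consensus_cluster(x, k = 4, resamples = 50, seed = 6)
  expect_setequal(cc$medoids, letters[1:4])
  expect_equal(unname(cc$consensus), rep(1, 4))
})

test_that("consensus subsets are invariant to feature order", {
  set.seed(7)
  z1 <- rnorm(40); z2 <- rnorm(40)
  x <- cbind(a = z1, b = z1 + rnorm(40, 0, 0.05), c = z2,
             d = z2 + rnorm(40, 0, 0.05))
  cc1 <- consensus_cluster(x, k = 2, resamples = 100, seed = 7)
  perm <- c("d", "b", "a", "c")
  cc2 <- consensus_cluster(x[, perm], k = 2, resamples = 100, seed = 7)
  same1 <- outer(cc1$assignment[perm], cc1$assignment[perm], "==")
  same2 <- outer(cc2$assignment, cc2$assignment, "==")
  expect_equal(unname(same1), unname(same2))
})

test_that("k grows until redundancy is resolved, or collapses to singletons", {
  set.seed(8)
  z <- rnorm(60)
  tight <- sapply(1:5, function(i) z + rnorm(60, 0, 0.1))
  colnames(tight) <- paste0("t", 1:5)
  ck <- choose_k_and_medoids(tight)
  expect_equal(ck$k, 2)                      # all |rho| > 0.9: accepted at once
  # an orthogonal feature must end up a singleton medoid
  x <- cbind(tight, lone = rnorm(60))
  ck2 <- choose_k_and_medoids(x)
  lone_subset <- ck2$assignment["lone"]
  expect_equal(sum(ck2$assignment == lone_subset), 1)
  expect_true("lone" %in% ck2$medoids)
})

test_that("the LASSO path shrinks to zero features and ranks by CV AUC", {
  set.seed(9)
  y <- make_labels()
  x <- cbind(sig = rnorm(52) + 1.5 * (y == "benefit"),
             matrix(rnorm(52 * 5), 52, 5))
  colnames(x) <- c("sig", paste0("n", 1:5))
  las <- lasso_select(x, y, seed = 9)
  expect_true(all(las$coefs[, 1] == 0))     # strongest penalty: empty model
  expect_true("sig" %in% las$selected)
  expect_equal(length(las$cv_auc), length(las$lambda))
  expect_true(all(las$cv_auc >= 0 & las$cv_auc <= 1))
  expect_true(las$lambda_chosen %in% las$lambda)
  expect_error(lasso_select(x[, 1, drop = FALSE], y), "at least 2")
})

test_that("screening is calibrated at the permutation null (quick check)", {
  set.seed(30)
  rates <- replicate(40, {
    y <- make_labels()
    x <- matrix(rnorm(52 * 25), 52, 25,
                dimnames = list(NULL, paste0("f", 1:25)))
    mean(univariate_screen(x, y)$retained)
  })
  expect_lt(abs(mean(rates) - 0.1), 0.025)
})

test_that("rank AUC agrees with an established ROC implementation", {
  set.seed(33)
  y <- make_labels(20, 25)
  v <- rnorm(45) + 0.8 * (y == "benefit")
  v[3] <- v[10]                       # include a tie
  ours <- feature_auc(v, y, n_boot = 0)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = v,
                                        levels = c("non-benefit", "benefit"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
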