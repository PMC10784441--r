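test_that("the catalog freezes 116 uniquely named features", {
  cat_df <- feature_catalog()
  expect_equal(nrow(cat_df), 116)
  expect_equal(anyDuplicated(cat_df$name), 0)
  expect_equal(sum(cat_df$family == "Shape"), 8)
  for (v in c("X", "XL", "XH")) {
    expect_equal(sum(cat_df$variant == v & cat_df$family == "H"), 14)
    expect_equal(sum(cat_df$variant == v & cat_df$family == "GLCM"), 13)
    expect_equal(sum(cat_df$variant == v & cat_df$family == "GLRLM"), 8)
    expect_equal(sum(cat_df$variant == v & cat_df$family == "F"), 1)
  }
  expect_true(all(c("XH_H_uniformity", "X_GLCM_contrast", "XL_GLRLM_LRHGLE",
                    "XH_GLCM_correlation", "XH_GLCM_cluster_shade",
                    "XL_H_mean_absolute_deviation") %in% cat_df$name))
})

test_that("discretization uses equal-width in-ROI bins with the constant convention", {
  img <- matrix(0:31, 8, 4)
  mask <- matrix(TRUE, 8, 4)
  expect_equal(sort(unique(as.vector(discretize(img, mask, 32)))), 1:32)
  expect_true(all(discretize(matrix(5, 4, 4), matrix(TRUE, 4, 4), 8) == 1,
                  na.rm = TRUE))
  lab <- discretize(matrix(c(0, 10, 20, 30), 2, 2), matrix(TRUE, 2, 2), 2)
  expect_equal(as.vector(lab), c(1, 1, 2, 2))
  expect_error(discretize(img, mask & FALSE, 2), "empty")
})

test_that("shape features behave on disks, rectangles and convex masks", {
  n <- 64
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  disk <- ((xx - 32.5)^2 + (yy - 32.5)^2) <= 20^2
  sf <- shape_features(disk, spacing = 0.5)
  expect_lt(abs(sf[["circularity"]] - 1), 0.1)
  expect_equal(sf[["area"]], sum(disk) * 0.25)
  expect_equal(sf[["solidity"]], 1)
  expect_lt(abs(sf[["major_axis"]] - 20), 1)    # 2r at 0.5 mm spacing

  square <- matrix(FALSE, 40, 40); square[11:30, 11:30] <- TRUE
  rect <- matrix(FALSE, 60, 60); rect[21:30, 11:50] <- TRUE   # same area
  expect_equal(shape_features(square)[["elongation"]], 1, tolerance = 1e-9)
  expect_gt(shape_features(rect)[["elongation"]],
            shape_features(square)[["elongation"]])
  expect_equal(shape_features(rect)[["solidity"]], 1)
  expect_error(shape_features(square & FALSE), "empty")
})

test_that("histogram features match hand arithmetic and degenerate rules", {
  v <- matrix(c(1, 2, 3, 4), 2, 2)
  m <- matrix(TRUE, 2, 2)
  hf <- histogram_features(v, m)
  expect_equal(hf[["mean"]], 2.5)
  expect_equal(hf[["mean_absolute_deviation"]], 1.0)
  expect_equal(hf[["range"]], 3)
  expect_equal(hf[["energy"]], 1 + 4 + 9 + 16)

  hc <- histogram_features(matrix(7, 3, 3), matrix(TRUE, 3, 3))
  expect_equal(hc[["variance"]], 0)
  expect_equal(hc[["entropy"]], 0)
  expect_equal(hc[["uniformity"]], 1)
  expect_equal(hc[["skewness"]], 0)

  two <- histogram_features(matrix(c(0, 0, 1, 1), 2, 2), m)
  expect_equal(two[["uniformity"]], 0.5)
  expect_equal(two[["entropy"]], 1)
})

test_that("histogram features are invariant to in-ROI pixel permutation", {
  set.seed(8)
  img <- matrix(rnorm(64), 8, 8)
  mask <- matrix(stats::runif(64) < 0.7, 8, 8); mask[1] <- TRUE
  img2 <- img
  img2[mask] <- sample(img[mask])
  expect_equal(histogram_features(img, mask), histogram_features(img2, mask))
})

test_that("GLCM features reproduce the enumerable special cases", {
  labc <- matrix(1L, 4, 4); attr(labc, "n_bins") <- 32L
  g <- glcm_features(labc)
  expect_equal(g[["contrast"]], 0)
  expect_equal(g[["energy"]], 1)
  expect_equal(g[["homogeneity"]], 1)
  expect_equal(g[["correlation"]], 1)   # zero-variance convention

  cb <- (outer(1:6, 1:6, "+") %% 2) + 1L   # strict checkerboard, levels 1/2
  attr(cb, "n_bins") <- 2L
  gh <- glcm_features(cb, directions = list(c(0, 1)))
  expect_equal(gh[["contrast"]], 1)
  expect_equal(gh[["energy"]], 0.5)
  expect_equal(gh[["cluster_shade"]], 0)  # levels symmetric about the mean

  # single pixel: no pairs, all-zero GLCM under the degenerate conventions
  one <- matrix(NA_integer_, 3, 3); one[2, 2] <- 1L
  attr(one, "n_bins") <- 4L
  g1 <- glcm_features(one)
  expect_equal(g1[["contrast"]], 0)
  expect_equal(g1[["energy"]], 0)
  expect_equal(g1[["correlation"]], 1)
})

test_that("GLCM matrices are symmetric, normalized, with gray-level marginals", {
  for (s in 1:5) {
    lab <- random_lab(s)
    P <- glcm_matrix(lab)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("GLCM and GLRLM match brute-force enumeration on 50 random ROIs", {
  for (s in 1:50) {
    lab <- random_lab(s)
    expect_equal(glcm_matrix(lab), oracle_glcm(lab), tolerance = 1e-10)
    expect_equal(glcm_features(lab), glcm_features(glcm = oracle_glcm(lab)),
                 tolerance = 1e-10)
    if (sum(!is.na(lab)) > 1)
      expect_equal(glrlm_features(lab), oracle_glrlm_features(lab),
                   tolerance = 1e-10)
  }
})

test_that("GLRLM features reproduce the enumerable run patterns", {
  labc <- matrix(1L, 4, 4); attr(labc, "n_bins") <- 2L
  r <- glrlm_features(labc, directions = list(c(0, 1)))
  expect_equal(r[["LRE"]], 16)
  expect_equal(r[["SRE"]], 1 / 16)
  expect_equal(r[["RP"]], 0.25)

  alt <- matrix(rep(c(1L, 2L), 8), 4, 4, byrow = TRUE)  # alternating along rows
  attr(alt, "n_bins") <- 2L
  ra <- glrlm_features(alt, directions = list(c(0, 1)))
  expect_equal(ra[["SRE"]], 1)
  expect_equal(ra[["LRE"]], 1)
})

test_that("fractal dimension is 2 for flat surfaces, rises with noise, ignores shifts", {
  flat <- matrix(3, 32, 32)
  m <- matrix(TRUE, 32, 32)
  expect_lt(abs(fractal_feature(flat, m) - 2), 0.05)
  set.seed(12)
  noisy <- matrix(rnorm(32 * 32, 0, 20), 32, 32)
  smoothed <- make_variants(noisy, sigma_smooth = 2)$XL
  expect_gt(fractal_feature(noisy, m), fractal_feature(smoothed, m))
  expect_equal(fractal_feature(noisy, m), fractal_feature(noisy + 500, m),
               tolerance = 1e-9)
  expect_error(fractal_feature(flat, matrix(c(TRUE, rep(FALSE, 1023)), 32, 32)),
               "8x8")
})

test_that("the handcrafted extractor emits the full deterministic 116-vector", {
  st <- get_test_study()
  v1 <- extract_handcrafted(st, st$roi1)
  expect_length(v1, 116)
  expect_identical(names(v1), feature_catalog()$name)
  expect_false(anyNA(v1))
  expect_length(attr(v1, "validity"), 0)
  expect_identical(unname(v1), unname(extract_handcrafted(st, st$roi1)))
})
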