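test_that("encoder construction is seed-deterministic and outputs a 5-simplex", {
  m1 <- build_encoder(seed = 3L)
  m2 <- build_encoder(seed = 3L)
  expect_identical(m1$params, m2$params)
  set.seed(1)
  x <- array(rnorm(64 * 64 * 3, 40, 30), c(64, 64, 3))
  p <- predict_pretext(m1, x)
  expect_equal(dim(p), c(3, 5))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("spatial sizes halve per block: 32, 16, 8, 4, with a GAP width of 8", {
  m <- build_encoder(seed = 2L)
  set.seed(2)
  x <- array(rnorm(64 * 64 * 2, 0, 10), c(64, 64, 1, 2))
  tr <- renomics:::encoder_trunk(m, x, cache = TRUE)
  sizes <- vapply(tr$caches, function(ca) dim(ca$mp$out)[1], numeric(1))
  expect_equal(sizes, c(32, 16, 8, 4))
  expect_equal(dim(tr$maps), c(4, 4, 8, 2))
  fwd <- renomics:::encoder_forward(m, x)
  expect_equal(nrow(fwd$gap), 8)
})

test_that("backpropagated gradients match central finite differences", {
  m <- build_encoder(seed = 5L)
  set.seed(5)
  xb <- array(rnorm(64 * 64 * 3, 0, 50), c(64, 64, 1, 3))
  yb <- matrix(0, 5, 3); yb[cbind(c(2, 4, 5), 1:3)] <- 1
  loss_of <- function(model) {
    f <- renomics:::encoder_forward(model, xb, train = TRUE, cache = TRUE,
                                    dropout_mask = matrix(1, 8, 3))
    list(fwd = f, loss = -mean(colSums(yb * log(pmax(f$probs, 1e-12)))))
  }
  base <- loss_of(m)
  grads <- renomics:::encoder_backward(m, base$fwd, yb, 0, 0)
  eps <- 1e-5
  probe <- list(
    list(g = grads$blocks[[1]]$conv1$W,
         set = function(mm, i, e) { mm$params$blocks[[1]]$conv1$W[i] <-
           mm$params$blocks[[1]]$conv1$W[i] + e; mm }),
    list(g = grads$blocks[[2]]$se$W2,
         set = function(mm, i, e) { mm$params$blocks[[2]]$se$W2[i] <-
           mm$params$blocks[[2]]$se$W2[i] + e; mm }),
    list(g = grads$blocks[[3]]$bn$beta,
         set = function(mm, i, e) { mm$params$blocks[[3]]$bn$beta[i] <-
           mm$params$blocks[[3]]$bn$beta[i] + e; mm }),
    list(g = grads$blocks[[4]]$skip$W,
         set = function(mm, i, e) { mm$params$blocks[[4]]$skip$W[i] <-
           mm$params$blocks[[4]]$skip$W[i] + e; mm }),
    list(g = grads$fc$W,
         set = function(mm, i, e) { mm$params$fc$W[i] <-
           mm$params$fc$W[i] + e; mm }))
  for (pr in probe) {
    for (i in 1:2) {
      num <- (loss_of(pr$set(m, i, eps))$loss -
              loss_of(pr$set(m, i, -eps))$loss) / (2 * eps)
      expect_equal(pr$g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("the plateau schedule drops the LR after 5 stagnant epochs and stops at best + 10", {
  st <- plateau_state(lr = 1e-3)
  # metric improves twice, then freezes
  for (metric in c(0.3, 0.4, rep(0.4, 20))) {
    st <- plateau_update(st, metric)
    if (st$stop) break
  }
  expect_true(st$stop)
  expect_equal(st$best_epoch, 2)
  expect_equal(st$epoch, 12)          # stop exactly at best + 10
  expect_equal(st$lr_drops, 2)        # at stagnation 5 and 10
  expect_equal(st$lr, 1e-3 * 0.01)
  # monotone improvement never stops or drops
  st2 <- plateau_state(lr = 1e-3)
  for (metric in seq(0.1, 0.9, length.out = 15)) st2 <- plateau_update(st2, metric)
  expect_false(st2$stop)
  expect_equal(st2$lr, 1e-3)
})

test_that("information-dense map selection follows FC weight mass with stable ties", {
  m <- build_encoder(seed = 4L)
  W <- matrix(0, 5, 8)
  W[, c(2, 3, 5, 6, 7, 8)] <- rnorm(30)
  while (any(colSums(abs(W[, c(2, 3, 5, 6, 7, 8)])) == 0))
    W[, c(2, 3, 5, 6, 7, 8)] <- rnorm(30)
  m$params$fc$W <- W
  expect_setequal(unname(select_information_dense_maps(m)), c(2, 3, 5, 6, 7, 8))
  # all-equal weights: the tie rule keeps the lowest channel indices
  m$params$fc$W <- matrix(1, 5, 8)
  expect_equal(unname(select_information_dense_maps(m)), 1:6)
  # ranking is invariant to permuting the class rows
  m$params$fc$W <- W
  sel1 <- select_information_dense_maps(m)
  m$params$fc$W <- W[c(3, 1, 5, 2, 4), ]
  expect_identical(select_information_dense_maps(m), sel1)
})

test_that("deep extraction yields the named 78-vector deterministically", {
  enc <- get_trained_encoder()
  st <- get_test_study()
  v <- extract_deep(enc, st, st$roi2)
  expect_length(v, 78)
  expect_identical(names(v), deep_feature_catalog()$name)
  expect_true(all(c("D1_GLCM_energy", "D5_GLCM_homogeneity2", "D1_node_mean")
                  %in% names(v)))
  expect_false(anyNA(v))
  expect_identical(v, extract_deep(enc, st, st$roi2))
  # a tiny ROI cannot cover one final-block cell
  tiny <- st$roi2 & FALSE
  tiny[50:55, 50:55] <- TRUE
  expect_error(extract_deep(enc, st, tiny), "feature-map cell")
})

test_that("pretext training rejects degenerate splits and logs its schedule", {
  ds <- get_pretext_data()
  bad <- ds
  bad$split[] <- "train"
  expect_error(train_pretext(build_encoder(), bad), "empty train or validation")
  enc <- get_trained_encoder()
  expect_true(all(c("epoch", "train_loss", "val_accuracy", "lr") %in%
                  colnames(enc$log)))
  expect_true(enc$trained)
  expect_length(enc$selected_channels, 6)
})

test_that("encoders round-trip through the JSON manifest", {
  enc <- get_trained_encoder()
  path <- withr::local_tempfile(fileext = ".json")
  save_encoder(enc, path)
  back <- load_encoder(path)
  st <- get_test_study()
  expect_equal(extract_deep(back, st, st$roi1), extract_deep(enc, st, st$roi1),
               tolerance = 1e-10)
})

test_that("strong L1 on the FC head zeroes out whole weight rows", {
  ds <- get_pretext_data()
  small <- list(x = ds$x[, , 1:160], y = ds$y[1:160],
                patient = ds$patient[1:160], split = ds$split[1:160])
  enc <- train_pretext(build_encoder(seed = 9L), small, epochs = 12L,
                       lr = 0.01, lambda1 = 1.5, lambda2 = 1e-4, seed = 9L)
  col_mass <- colSums(abs(enc$params$fc$W))
  expect_gte(sum(col_mass < 1e-3), 2)     # whole GAP-node rows switched off
  expect_gte(sum(col_mass > 0.05), 2)     # while informative rows survive
})
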