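# Self-supervised pretext encoder: four convolutional blocks, each
# [2x2 conv -> 8ch, 2x2 conv -> 8ch, batch norm, ReLU, squeeze-excitation,
# + 1x1-conv skip], followed by 2x2 max pooling; global average pooling to an
# 8-vector, dropout, and a fully connected 5-class softmax head. The network
# is trained to recognize which of five degradations a 64x64 patch received;
# outcome labels are never visible to this module. Deep features are read off
# the information-dense channels of the final block.

DEEP_H_STATS <- c("variance", "skewness", "kurtosis", "entropy", "uniformity",
                  "range")
DEEP_GLCM_STATS <- c("contrast", "correlation", "energy", "entropy",
                     "homogeneity2", "cluster_shade")

#' Architecture specification of the pretext encoder
#'
#' @param n_blocks number of convolutional blocks (4).
#' @param channels output channels of every convolution (8).
#' @param se_reduction squeeze-excitation bottleneck reduction factor.
#' @param dropout dropout probability before the fully connected head.
#' @param n_classes number of pretext classes (the five degradation kinds).
#' @param input_scale fixed multiplicative input normalization (0.01, i.e.
#'   HU / 100, bringing soft-tissue intensities to unit order).
#' @export
encoder_spec <- function(n_blocks = 4L, channels = 8L, se_reduction = 2L,
                         dropout = 0.25, n_classes = 5L, input_scale = 0.01) {
  structure(list(n_blocks = n_blocks, channels = channels,
                 se_reduction = se_reduction, dropout = dropout,
                 n_classes = n_classes, input_scale = input_scale),
            class = "encoder_spec")
}

#' Build an untrained pretext encoder
#'
#' He-normal initialization, reproducible from the seed alone.
#'
#' @param spec an [encoder_spec()].
#' @param seed integer seed.
#' @return An object of class `pretext_encoder`.
#' @export
build_encoder <- function(spec = encoder_spec(), seed = 1L) {
  ch <- spec$channels
  r <- max(1L, ch %/% spec$se_reduction)
  with_seed(seed, {
    he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0,
                                                       sqrt(2 / fan_in)), nr, nc)
    blocks <- lapply(seq_len(spec$n_blocks), function(b) {
      cin <- if (b == 1) 1L else ch
      list(conv1 = list(W = he(4L * cin, ch, 4L * cin), b = rep(0, ch)),
           conv2 = list(W = he(4L * ch, ch, 4L * ch), b = rep(0, ch)),
           bn = list(gamma = rep(1, ch), beta = rep(0, ch)),
           se = list(W1 = he(r, ch, ch), b1 = rep(0, r),
                     W2 = he(ch, r, r), b2 = rep(0, ch)),
           skip = list(W = he(cin, ch, cin), b = rep(0, ch)))
    })
    fc <- list(W = he(spec$n_classes, ch, ch), b = rep(0, spec$n_classes))
    running <- lapply(seq_len(spec$n_blocks), function(b)
      list(mean = rep(0, ch), var = rep(1, ch)))
    structure(list(spec = spec, params = list(blocks = blocks, fc = fc),
                   bn_running = running, trained = FALSE, log = NULL,
                   selected_channels = NULL, seed = seed),
              class = "pretext_encoder")
  })
}

# Forward through the convolutional trunk. Returns final post-pool maps and,
# if cache = TRUE, everything needed for backprop.
encoder_trunk <- function(model, x, train = FALSE, cache = FALSE) {
  x <- x * model$spec$input_scale
  caches <- if (cache) vector("list", model$spec$n_blocks)
  running <- model$bn_running
  for (b in seq_len(model$spec$n_blocks)) {
    pb <- model$params$blocks[[b]]
    c1 <- conv2x2_forward(x, pb$conv1$W, pb$conv1$b)
    c2 <- conv2x2_forward(c1$out, pb$conv2$W, pb$conv2$b)
    bn <- bn_forward(c2$out, pb$bn$gamma, pb$bn$beta, running[[b]], train)
    running[[b]] <- bn$running
    relu <- pmax(bn$out, 0)
    se <- se_forward(relu, pb$se)
    sk <- conv1x1_forward(x, pb$skip$W, pb$skip$b)
    summed <- se$out + sk$out
    mp <- maxpool2_forward(summed)
    if (cache)
      caches[[b]] <- list(c1 = c1, c2 = c2, bn = bn, relu = relu, se = se,
                          sk = sk, mp = mp, x_in_dim = dim(x))
    x <- mp$out
  }
  list(maps = x, caches = caches, running = running)
}

# Full forward: probabilities, GAP vector, final maps.
encoder_forward <- function(model, x, train = FALSE, cache = FALSE,
                            dropout_mask = NULL) {
  if (length(dim(x)) == 3) x <- array(x, c(dim(x)[1:2], 1L, dim(x)[3]))
  tr <- encoder_trunk(model, x, train, cache)
  gap <- apply(tr$maps, c(3, 4), mean)                   # C x N
  gap_d <- gap
  if (train) {
    if (is.null(dropout_mask)) {
      p <- model$spec$dropout
      dropout_mask <- matrix(stats::rbinom(length(gap), 1, 1 - p) / (1 - p),
                             nrow(gap), ncol(gap))
    }
    gap_d <- gap * dropout_mask
  }
  logits <- model$params$fc$W %*% gap_d + model$params$fc$b  # K x N
  probs <- t(softmax_rows(t(logits)))                        # K x N
  list(probs = probs, gap = gap, gap_d = gap_d, maps = tr$maps,
       caches = tr$caches, running = tr$running, dropout_mask = dropout_mask)
}

# Backward pass for one minibatch; y_onehot is K x N. Returns gradient tree
# shaped like model$params (FC regularization gradient included).
encoder_backward <- function(model, fwd, y_onehot, lambda1, lambda2) {
  N <- ncol(y_onehot)
  dlogits <- (fwd$probs - y_onehot) / N                      # K x N
  fcW <- model$params$fc$W
  # L2 enters the gradient; L1 is applied as a proximal soft-threshold after
  # the optimizer step (see train_pretext), which produces exact zeros
  dfcW <- tcrossprod(dlogits, fwd$gap_d) + 2 * lambda2 * fcW
  dfcb <- rowSums(dlogits)
  dgap <- crossprod(fcW, dlogits)                            # C x N
  if (!is.null(fwd$dropout_mask)) dgap <- dgap * fwd$dropout_mask
  d <- dim(fwd$maps)
  dmaps <- aperm(array(rep(dgap / (d[1] * d[2]), each = d[1] * d[2]),
                       c(d[1], d[2], d[3], d[4])), c(1, 2, 3, 4))
  gblocks <- vector("list", model$spec$n_blocks)
  dy <- dmaps
  for (b in rev(seq_len(model$spec$n_blocks))) {
    pb <- model$params$blocks[[b]]
    ca <- fwd$caches[[b]]
    dsum <- maxpool2_backward(dy, ca$mp)
    dsk <- conv1x1_backward(dsum, ca$sk, pb$skip$W)
    dse <- se_backward(dsum, ca$se, ca$relu, pb$se)
    drelu <- dse$dx
    drelu[ca$relu <= 0] <- 0
    dbn <- bn_backward(drelu, ca$bn, pb$bn$gamma)
    dc2 <- conv2x2_backward(dbn$dx, ca$c2, pb$conv2$W)
    dc1 <- conv2x2_backward(dc2$dx, ca$c1, pb$conv1$W)
    gblocks[[b]] <- list(
      conv1 = list(W = dc1$dW, b = dc1$db),
      conv2 = list(W = dc2$dW, b = dc2$db),
      bn = list(gamma = dbn$dgamma, beta = dbn$dbeta),
      se = list(W1 = dse$dW1, b1 = dse$db1, W2 = dse$dW2, b2 = dse$db2),
      skip = list(W = dsk$dW, b = dsk$db))
    dy <- dc1$dx + dsk$dx
  }
  list(blocks = gblocks, fc = list(W = dfcW, b = dfcb))
}

#' Predict degradation-class probabilities for patches
#'
#' @param model a `pretext_encoder`.
#' @param x a 64x64 matrix or a 64 x 64 x N array.
#' @return An N x 5 matrix of class probabilities (rows sum to 1).
#' @export
predict_pretext <- function(model, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  t(encoder_forward(model, x)$probs)
}

# ---- plateau learning-rate schedule / early stopping ----------------------

#' Initialize the plateau training schedule state
#'
#' The learning rate is multiplied by `factor` after `patience_lr` consecutive
#' epochs without validation improvement, and training halts after
#' `patience_stop` such epochs.
#'
#' @param lr initial learning rate.
#' @param patience_lr epochs without improvement before an LR drop (5).
#' @param patience_stop epochs without improvement before stopping (10).
#' @param factor multiplicative LR drop (0.1).
#' @export
plateau_state <- function(lr = 1e-3, patience_lr = 5L, patience_stop = 10L,
                          factor = 0.1) {
  list(lr = lr, best = -Inf, since = 0L, stop = FALSE, lr_drops = 0L,
       patience_lr = patience_lr, patience_stop = patience_stop,
       factor = factor, best_epoch = 0L, epoch = 0L)
}

#' Advance the plateau schedule by one epoch
#'
#' @param state a [plateau_state()].
#' @param metric this epoch's validation metric (higher is better).
#' @return Updated state: `lr`, `stop`, `lr_drops`, `best`, `best_epoch`.
#' @export
plateau_update <- function(state, metric) {
  state$epoch <- state$epoch + 1L
  if (metric > state$best) {
    state$best <- metric
    state$best_epoch <- state$epoch
    state$since <- 0L
  } else {
    state$since <- state$since + 1L
    if (state$since %% state$patience_lr == 0L) {
      state$lr <- state$lr * state$factor
      state$lr_drops <- state$lr_drops + 1L
    }
    if (state$since >= state$patience_stop) state$stop <- TRUE
  }
  state
}

#' Train the pretext encoder by degradation classification
#'
#' Minimizes the categorical cross-entropy of the five-class degradation
#' labels with Adam, L1-L2 regularization on the fully connected layer,
#' a plateau learning-rate schedule (x0.1 after 5 stagnant epochs) and early
#' stopping (after 10 stagnant epochs). Validation accuracy is monitored on
#' the patient-disjoint validation split.
#'
#' @param model an untrained [build_encoder()] result.
#' @param data a [build_pretext_dataset()] result (`x`, `y`, `split`).
#' @param epochs maximum epochs.
#' @param batch_size minibatch size (32).
#' @param lr initial Adam learning rate (1e-3).
#' @param lambda1,lambda2 L1 and L2 penalties on the FC weights (1e-4).
#' @param seed integer seed for shuffling, dropout and initialization order.
#' @return The trained `pretext_encoder` with a per-epoch `log` (epoch,
#'   train_loss, val_accuracy, lr), `stop_epoch`, `lr_drops` and
#'   `selected_channels`.
#' @export
train_pretext <- function(model, data, epochs = 30L, batch_size = 32L,
                          lr = 1e-3, lambda1 = 1e-4, lambda2 = 1e-4,
                          seed = 1L) {
  stopifnot(inherits(model, "pretext_encoder"))
  tr_idx <- which(data$split == "train")
  va_idx <- which(data$split == "val")
  assert_that(length(tr_idx) > 0 && length(va_idx) > 0,
              "empty train or validation split")
  stopifnot(!anyNA(data$y))
  K <- model$spec$n_classes
  y_int <- as.integer(data$y)
  onehot <- function(idx) {
    m <- matrix(0, K, length(idx))
    m[cbind(y_int[idx], seq_along(idx))] <- 1
    m
  }
  state <- adam_init(model$params)
  sched <- plateau_state(lr)
  log_rows <- list()
  t_step <- 0L
  with_seed(derive_seed(seed, 3L), {
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      losses <- numeric(0)
      for (start in seq(1, length(ord), batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, length(ord))]
        if (length(bi) < 2) next      # batch norm needs > 1 sample
        xb <- data$x[, , bi, drop = FALSE]
        yb <- onehot(bi)
        fwd <- encoder_forward(model, xb, train = TRUE, cache = TRUE)
        model$bn_running <- fwd$running
        p <- pmax(fwd$probs, 1e-12)
        losses <- c(losses, -mean(colSums(yb * log(p))))
        grads <- encoder_backward(model, fwd, yb, lambda1, lambda2)
        t_step <- t_step + 1L
        upd <- adam_step(model$params, grads, state, sched$lr, t_step)
        model$params <- upd$p
        state <- upd$s
        # proximal L1 on the fully connected weights: exact sparsification
        W <- model$params$fc$W
        model$params$fc$W <- sign(W) * pmax(abs(W) - sched$lr * lambda1, 0)
      }
      val_acc <- mean(apply(predict_pretext(model, data$x[, , va_idx, drop = FALSE]),
                            1, which.max) == y_int[va_idx])
      sched <- plateau_update(sched, val_acc)
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                                   val_accuracy = val_acc, lr = sched$lr)
      if (sched$stop) break
    }
  })
  model$trained <- TRUE
  model$log <- do.call(rbind, log_rows)
  model$stop_epoch <- nrow(model$log)
  model$lr_drops <- sched$lr_drops
  model$best_val_accuracy <- sched$best
  model$selected_channels <- select_information_dense_maps(model)
  model
}

#' Select the information-dense feature-map channels
#'
#' Channels of the final block are ranked by the total absolute fully
#' connected weight mass attached to their GAP node (summed over classes);
#' the top `n_maps` are kept and renamed D1..Dn in rank order. Ties break
#' toward the lower channel index. The selection is a function of the weights
#' alone.
#'
#' @param model a `pretext_encoder`.
#' @param n_maps number of channels to keep (6).
#' @return Named integer vector (names `D1`..`Dn`, values channel indices).
#' @export
select_information_dense_maps <- function(model, n_maps = 6L) {
  W <- model$params$fc$W
  mass <- colSums(abs(W))
  ord <- order(-mass, seq_along(mass))[seq_len(n_maps)]
  stats::setNames(ord, paste0("D", seq_len(n_maps)))
}

#' The deep feature catalog
#'
#' Thirteen statistics per selected map: the ROI mean of the map
#' (`Dk_node_mean`), six histogram statistics (`Dk_H_*`) and six GLCM
#' statistics (`Dk_GLCM_*`), for maps D1..D6: 6 x 13 = 78 named features.
#'
#' @param n_maps number of selected maps (6).
#' @return data.frame with columns `name`, `map`, `family`, `stat`.
#' @export
deep_feature_catalog <- function(n_maps = 6L) {
  do.call(rbind, lapply(seq_len(n_maps), function(k) {
    d <- paste0("D", k)
    data.frame(
      name = c(paste0(d, "_node_mean"), paste0(d, "_H_", DEEP_H_STATS),
               paste0(d, "_GLCM_", DEEP_GLCM_STATS)),
      map = d,
      family = c("node", rep("H", length(DEEP_H_STATS)),
                 rep("GLCM", length(DEEP_GLCM_STATS))),
      stat = c("node_mean", DEEP_H_STATS, DEEP_GLCM_STATS),
      stringsAsFactors = FALSE)
  }))
}

# Reflect-pad a matrix on the bottom/right so both dims divide `mult`.
pad_to_multiple <- function(img, mult) {
  h <- nrow(img); w <- ncol(img)
  h2 <- ceiling(h / mult) * mult; w2 <- ceiling(w / mult) * mult
  if (h2 == h && w2 == w) return(img)
  ridx <- c(seq_len(h), h - seq_len(h2 - h))
  cidx <- c(seq_len(w), w - seq_len(w2 - w))
  img[ridx, cidx, drop = FALSE]
}

#' Extract the 78 deep features for one ROI
#'
#' Runs the trained convolutional trunk fully convolutionally over the whole
#' standardized slice X, bilinearly upsamples each selected final-block map to
#' the image grid, and computes 13 statistics per map over the ROI (map
#' discretized with 16 gray levels for the GLCM block).
#'
#' @param model a trained `pretext_encoder` with selected channels.
#' @param study a `preprocessed_study`.
#' @param mask logical ROI matrix on the study grid; its bounding box must
#'   cover at least one final-block feature-map cell (16 x 16 input pixels).
#' @param n_bins gray levels for the on-map GLCM (16).
#' @return Named numeric vector of length 78 in [deep_feature_catalog()] order.
#' @export
extract_deep <- function(model, study, mask, n_bins = 16L) {
  stopifnot(inherits(model, "pretext_encoder"))
  assert_that(isTRUE(model$trained), "encoder must be trained first")
  sel <- model$selected_channels
  if (is.null(sel)) sel <- select_information_dense_maps(model)
  assert_that(any(mask), "mask is empty")
  bb <- mask_bbox(mask)
  cell <- 2^model$spec$n_blocks
  assert_that(length(bb$rows) >= cell && length(bb$cols) >= cell,
              "ROI bounding box smaller than one feature-map cell (%dx%d px)",
              cell, cell)
  img <- pad_to_multiple(study$X, cell)
  tr <- encoder_trunk(model, array(img, c(dim(img), 1L, 1L)), train = FALSE)
  H <- nrow(study$X); W <- ncol(study$X)
  hm <- dim(tr$maps)[1]; wm <- dim(tr$maps)[2]
  ph <- nrow(img); pw <- ncol(img)
  # pixel-center mapping from the padded image grid into map coordinates
  yy <- matrix((seq_len(ph) - 0.5) * hm / ph + 0.5, ph, pw)
  xx <- matrix((seq_len(pw) - 0.5) * wm / pw + 0.5, ph, pw, byrow = TRUE)
  out <- numeric(0)
  for (k in seq_along(sel)) {
    map_small <- tr$maps[, , sel[k], 1]
    up <- bilinear_sample(map_small, yy, xx)[seq_len(H), seq_len(W)]
    node_mean <- mean(up[mask])
    hs <- histogram_features(up, mask, n_bins)[DEEP_H_STATS]
    lab <- discretize(up, mask, n_bins)
    gs <- glcm_features(lab)[DEEP_GLCM_STATS]
    v <- c(node_mean, hs, gs)
    names(v) <- c(paste0(names(sel)[k], "_node_mean"),
                  paste0(names(sel)[k], "_H_", DEEP_H_STATS),
                  paste0(names(sel)[k], "_GLCM_", DEEP_GLCM_STATS))
    out <- c(out, v)
  }
  out
}

#' Serialize a pretext encoder to JSON (architecture manifest plus weights)
#' @param model a `pretext_encoder`.
#' @param path output path.
#' @export
save_encoder <- function(model, path) {
  ser <- list(spec = unclass(model$spec),
              params = model$params,
              bn_running = model$bn_running,
              trained = model$trained,
              selected_channels = as.list(model$selected_channels),
              log = model$log)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a pretext encoder saved by [save_encoder()]
#' @param path JSON path.
#' @export
load_encoder <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  spec <- do.call(encoder_spec, ser$spec)
  model <- build_encoder(spec, seed = 1L)
  ch <- spec$channels
  fix_mat <- function(m, nr, nc) matrix(as.numeric(m), nr, nc)
  for (b in seq_len(spec$n_blocks)) {
    pb <- ser$params$blocks[[b]]
    cin <- if (b == 1) 1L else ch
    r <- max(1L, ch %/% spec$se_reduction)
    model$params$blocks[[b]] <- list(
      conv1 = list(W = fix_mat(pb$conv1$W, 4L * cin, ch), b = as.numeric(pb$conv1$b)),
      conv2 = list(W = fix_mat(pb$conv2$W, 4L * ch, ch), b = as.numeric(pb$conv2$b)),
      bn = list(gamma = as.numeric(pb$bn$gamma), beta = as.numeric(pb$bn$beta)),
      se = list(W1 = fix_mat(pb$se$W1, r, ch), b1 = as.numeric(pb$se$b1),
                W2 = fix_mat(pb$se$W2, ch, r), b2 = as.numeric(pb$se$b2)),
      skip = list(W = fix_mat(pb$skip$W, cin, ch), b = as.numeric(pb$skip$b)))
    model$bn_running[[b]] <- list(mean = as.numeric(ser$bn_running[[b]]$mean),
                                  var = as.numeric(ser$bn_running[[b]]$var))
  }
  model$params$fc <- list(W = fix_mat(ser$params$fc$W, spec$n_classes, ch),
                          b = as.numeric(ser$params$fc$b))
  model$trained <- isTRUE(ser$trained)
  model$selected_channels <- stats::setNames(unlist(ser$selected_channels),
                                             names(ser$selected_channels))
  if (!is.null(ser$log))
    model$log <- do.call(rbind, lapply(ser$log, as.data.frame))
  model
}
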