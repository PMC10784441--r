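# Minimal dense-tensor neural network layers used by the pretext encoder:
# 2x2 "same" convolution via shifted-slice im2col, batch normalization,
# ReLU, squeeze-and-excitation channel attention, 1x1 skip convolution,
# 2x2 max pooling, global average pooling, dropout, fully connected softmax
# head, and Adam. Tensors are arrays of shape (H, W, C, N).

nn_pad_br <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 1L, d[2] + 1L, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  out
}

# 2x2 convolution, stride 1, zero pad bottom/right so output size = input size.
# W is a (4*C_in) x C_out matrix, column block order: offset-major (the four
# kernel offsets (0,0),(0,1),(1,0),(1,1)), channel within offset.
conv2x2_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  xp <- nn_pad_br(x)
  M <- matrix(0, H * Wd * N, 4L * C)
  k <- 0L
  for (off in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
    sl <- xp[off[1] + seq_len(H), off[2] + seq_len(Wd), , , drop = FALSE]
    # (H,W,C,N) -> columns per channel with row order vec(H,W,N)
    sl <- aperm(sl, c(1, 2, 4, 3))
    M[, k + seq_len(C)] <- matrix(sl, H * Wd * N, C)
    k <- k + C
  }
  y <- M %*% W
  y <- sweep(y, 2, b, "+")
  out <- aperm(array(y, c(H, Wd, N, ncol(W))), c(1, 2, 4, 3))
  list(out = out, M = M, dim_in = d)
}

conv2x2_backward <- function(dy, cache, W) {
  d <- cache$dim_in; H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  Co <- ncol(W)
  dymat <- matrix(aperm(dy, c(1, 2, 4, 3)), H * Wd * N, Co)
  dW <- crossprod(cache$M, dymat)
  db <- colSums(dymat)
  dM <- tcrossprod(dymat, W)
  dxp <- array(0, c(H + 1L, Wd + 1L, C, N))
  k <- 0L
  for (off in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
    blk <- array(dM[, k + seq_len(C)], c(H, Wd, N, C))
    dxp[off[1] + seq_len(H), off[2] + seq_len(Wd), , ] <-
      dxp[off[1] + seq_len(H), off[2] + seq_len(Wd), , , drop = FALSE] +
      aperm(blk, c(1, 2, 4, 3))
    k <- k + C
  }
  list(dx = dxp[seq_len(H), seq_len(Wd), , , drop = FALSE], dW = dW, db = db)
}

conv1x1_forward <- function(x, W, b) {
  d <- dim(x)
  M <- matrix(aperm(x, c(1, 2, 4, 3)), prod(d[c(1, 2, 4)]), d[3])
  y <- sweep(M %*% W, 2, b, "+")
  list(out = aperm(array(y, c(d[1], d[2], d[4], ncol(W))), c(1, 2, 4, 3)),
       M = M, dim_in = d)
}

conv1x1_backward <- function(dy, cache, W) {
  d <- cache$dim_in
  dymat <- matrix(aperm(dy, c(1, 2, 4, 3)), prod(d[c(1, 2, 4)]), ncol(W))
  dM <- tcrossprod(dymat, W)
  list(dx = aperm(array(dM, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)),
       dW = crossprod(cache$M, dymat), db = colSums(dymat))
}

bn_forward <- function(x, gamma, beta, running, train, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean; va <- running$var
  }
  xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(va + eps), "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = aperm(array(y, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)),
       xhat = xhat, inv_sd = 1 / sqrt(va + eps), running = running, dim_in = d)
}

bn_backward <- function(dy, cache, gamma) {
  d <- cache$dim_in; C <- d[3]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  m <- nrow(dym)
  t1 <- sweep(dym, 2, colMeans(dym))
  t2 <- sweep(xhat, 2, colSums(dym * xhat) / m, "*")
  dx <- sweep((t1 - t2), 2, gamma * cache$inv_sd, "*")
  list(dx = aperm(array(dx, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)),
       dgamma = dgamma, dbeta = dbeta)
}

se_forward <- function(x, p) {
  d <- dim(x); C <- d[3]; N <- d[4]
  z <- apply(x, c(3, 4), mean)                      # C x N
  a <- pmax(p$W1 %*% z + p$b1, 0)                   # r x N
  s <- p$W2 %*% a + p$b2                            # C x N
  g <- 1 / (1 + exp(-s))
  gx <- aperm(array(rep(g, each = d[1] * d[2]), c(d[1], d[2], C, N)), c(1, 2, 3, 4))
  list(out = x * gx, z = z, a = a, g = g, gx = gx, dim_in = d)
}

se_backward <- function(dy, cache, x, p) {
  d <- cache$dim_in; C <- d[3]; N <- d[4]
  dx <- dy * cache$gx
  dg <- apply(dy * x, c(3, 4), sum)                 # C x N
  ds <- dg * cache$g * (1 - cache$g)
  dW2 <- tcrossprod(ds, cache$a)
  db2 <- rowSums(ds)
  da <- crossprod(p$W2, ds)
  da[cache$a <= 0] <- 0
  dW1 <- tcrossprod(da, cache$z)
  db1 <- rowSums(da)
  dz <- crossprod(p$W1, da)                         # C x N
  dzx <- aperm(array(rep(dz / (d[1] * d[2]), each = d[1] * d[2]),
                     c(d[1], d[2], C, N)), c(1, 2, 3, 4))
  list(dx = dx + dzx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  ro <- seq(1, d[1], 2); co <- seq(1, d[2], 2)
  cand <- array(0, c(length(ro), length(co), d[3], d[4], 4))
  cand[, , , , 1] <- x[ro, co, , , drop = FALSE]
  cand[, , , , 2] <- x[ro + 1, co, , , drop = FALSE]
  cand[, , , , 3] <- x[ro, co + 1, , , drop = FALSE]
  cand[, , , , 4] <- x[ro + 1, co + 1, , , drop = FALSE]
  dd <- c(length(ro), length(co), d[3], d[4])
  sl <- function(k) array(cand[, , , , k], dd)
  out <- pmax(sl(1), sl(2), sl(3), sl(4))
  arg <- (sl(1) == out) * 1
  arg[arg == 0 & sl(2) == out] <- 2
  arg[arg == 0 & sl(3) == out] <- 3
  arg[arg == 0] <- 4
  list(out = out, arg = arg, dim_in = d)
}

maxpool2_backward <- function(dy, cache) {
  d <- cache$dim_in
  dx <- array(0, d)
  ro <- seq(1, d[1], 2); co <- seq(1, d[2], 2)
  for (k in 1:4) {
    sel <- cache$arg == k
    blk <- dy * sel
    rr <- ro + (k == 2 || k == 4); cc <- co + (k == 3 || k == 4)
    dx[rr, cc, , ] <- dx[rr, cc, , , drop = FALSE] + blk
  }
  dx
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam over a nested parameter list -----------------------------------

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    list(m = p * 0, v = p * 0)
  }
  walk(params)
}

# Updates params in lockstep with an identically shaped gradient list.
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p) && !identical(names(p), c("m", "v"))) {
      out <- mapply(walk, p, g, s, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), s = lapply(out, `[[`, "s")))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk(params, grads, state)
}
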