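# Brute-force texture oracles: literal pair / run enumeration, independent
# of the vectorized implementations they check, shared across test files.

oracle_glcm <- function(lab, distance = 1L) {
  nb <- attr(lab, "n_bins")
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- matrix(0, nb, nb)
  for (d in dirs) {
    g <- matrix(0, nb, nb)
    for (r in seq_len(nrow(lab))) for (cc in seq_len(ncol(lab))) {
      r2 <- r + d[1] * distance; c2 <- cc + d[2] * distance
      if (r2 < 1 || r2 > nrow(lab) || c2 < 1 || c2 > ncol(lab)) next
      a <- lab[r, cc]; b <- lab[r2, c2]
      if (is.na(a) || is.na(b)) next
      g[a, b] <- g[a, b] + 1
      g[b, a] <- g[b, a] + 1
    }
    if (sum(g) > 0) acc <- acc + g / sum(g)
  }
  if (sum(acc) > 0) acc / sum(acc) else acc
}

oracle_glrlm_features <- function(lab) {
  nb <- attr(lab, "n_bins")
  np <- sum(!is.na(lab))
  h <- nrow(lab); w <- ncol(lab)
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  per_dir <- sapply(dirs, function(d) {
    R <- matrix(0, nb, max(h, w))
    visited <- matrix(FALSE, h, w)
    for (r in seq_len(h)) for (cc in seq_len(w)) {
      if (is.na(lab[r, cc]) || visited[r, cc]) next
      # start of a run only if the previous cell along the direction differs
      pr <- r - d[1]; pc <- cc - d[2]
      prev_same <- pr >= 1 && pr <= h && pc >= 1 && pc <= w &&
        !is.na(lab[pr, pc]) && lab[pr, pc] == lab[r, cc]
      if (prev_same) next
      len <- 0L; rr <- r; c2 <- cc
      while (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w &&
             !is.na(lab[rr, c2]) && lab[rr, c2] == lab[r, cc]) {
        visited[rr, c2] <- TRUE
        len <- len + 1L
        rr <- rr + d[1]; c2 <- c2 + d[2]
      }
      R[lab[r, cc], len] <- R[lab[r, cc], len] + 1
    }
    nr <- sum(R)
    i <- matrix(seq_len(nb), nb, ncol(R))
    l <- t(matrix(seq_len(ncol(R)), ncol(R), nb))
    c(SRE = sum(R / l^2) / nr, LRE = sum(R * l^2) / nr,
      GLN = sum(rowSums(R)^2) / nr, RLN = sum(colSums(R)^2) / nr,
      RP = nr / np, LGRE = sum(R / i^2) / nr, HGRE = sum(R * i^2) / nr,
      LRHGLE = sum(R * i^2 / l^2) / nr)
  })
  rowMeans(per_dir)
}

random_lab <- function(seed, nb = 4L) {
  set.seed(seed)
  lab <- matrix(sample.int(nb, 64, replace = TRUE), 8, 8)
  lab[matrix(stats::runif(64) < 0.2, 8, 8)] <- NA   # ragged ROI
  if (all(is.na(lab))) lab[1, 1] <- 1L
  attr(lab, "n_bins") <- nb
  lab
}

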