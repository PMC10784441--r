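# Handcrafted radiomics features over the X/XL/XH triple: 8 mask-only shape
# features plus, per image variant, 14 histogram, 13 GLCM, 8 GLRLM and 1
# fractal feature = 8 + 3 * 36 = 116. Formulas follow IBSI-style definitions;
# gray-level discretization is fixed-bin-number over the in-ROI range.

HIST_STATS <- c("mean", "variance", "standard_deviation", "skewness",
                "kurtosis", "median", "minimum", "maximum", "range",
                "interquartile_range", "mean_absolute_deviation", "energy",
                "entropy", "uniformity")
GLCM_STATS <- c("contrast", "correlation", "energy", "entropy", "homogeneity",
                "homogeneity2", "dissimilarity", "cluster_shade",
                "cluster_prominence", "autocorrelation", "sum_average",
                "sum_entropy", "maximum_probability")
GLRLM_STATS <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "LRHGLE")
SHAPE_STATS <- c("area", "perimeter", "perimeter_area_ratio", "circularity",
                 "major_axis", "minor_axis", "elongation", "solidity")

#' The frozen handcrafted feature catalog
#'
#' Naming scheme `<variant>_<family>_<stat>`: `Shape_*` (mask-only, computed
#' once), then per variant X, XL, XH: `H` histogram (14), `GLCM` (13), `GLRLM`
#' (8), `F` fractal (1). 8 + 3*(14+13+8+1) = 116 unique ordered names.
#'
#' @return data.frame with columns `name`, `variant`, `family`, `stat`.
#' @export
feature_catalog <- function() {
  rows <- data.frame(name = paste0("Shape_", SHAPE_STATS), variant = "mask",
                     family = "Shape", stat = SHAPE_STATS,
                     stringsAsFactors = FALSE)
  for (v in c("X", "XL", "XH")) {
    rows <- rbind(rows,
      data.frame(name = paste0(v, "_H_", HIST_STATS), variant = v,
                 family = "H", stat = HIST_STATS, stringsAsFactors = FALSE),
      data.frame(name = paste0(v, "_GLCM_", GLCM_STATS), variant = v,
                 family = "GLCM", stat = GLCM_STATS, stringsAsFactors = FALSE),
      data.frame(name = paste0(v, "_GLRLM_", GLRLM_STATS), variant = v,
                 family = "GLRLM", stat = GLRLM_STATS, stringsAsFactors = FALSE),
      data.frame(name = paste0(v, "_F_dimension"), variant = v,
                 family = "F", stat = "dimension", stringsAsFactors = FALSE))
  }
  rows
}

#' Export the feature catalog as JSON
#' @param path output file path.
#' @export
write_catalog_json <- function(path) {
  jsonlite::write_json(feature_catalog(), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Discretize ROI intensities into gray levels
#'
#' Equal-width bins over the in-ROI min-max range (fixed bin number), labels
#' 1..n_bins. A constant ROI maps every pixel to bin 1 by convention.
#'
#' @param img numeric matrix.
#' @param mask logical matrix, non-empty.
#' @param n_bins number of gray levels (>= 2).
#' @return Integer matrix of the ROI bounding box with labels inside the ROI
#'   and `NA` outside, plus attribute `n_bins`.
#' @export
discretize <- function(img, mask, n_bins = 32L) {
  assert_that(any(mask), "mask is empty")
  assert_that(n_bins >= 2, "n_bins must be >= 2")
  bb <- mask_bbox(mask)
  v <- img[bb$rows, bb$cols, drop = FALSE]
  m <- mask[bb$rows, bb$cols, drop = FALSE]
  lo <- min(v[m]); hi <- max(v[m])
  lab <- matrix(NA_integer_, nrow(v), ncol(v))
  if (hi - lo < .Machine$double.eps) {
    lab[m] <- 1L
  } else {
    wbin <- (hi - lo) / n_bins
    lab[m] <- pmin(as.integer(floor((v[m] - lo) / wbin)) + 1L, n_bins)
  }
  attr(lab, "n_bins") <- as.integer(n_bins)
  lab
}

mask_bbox <- function(mask) {
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  list(rows = rows[1]:rows[2], cols = cols[1]:cols[2])
}

# Largest 4/8-connected component via flood fill (masks here are small).
largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  h <- nrow(mask); w <- ncol(mask)
  cur <- 0L
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    stack <- todo[1]
    lab[stack] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% h + 1L; cc <- (p - 1L) %/% h + 1L
      nr <- r + offs[, 1]; nc <- cc + offs[, 2]
      ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
      q <- (nc[ok] - 1L) * h + nr[ok]
      q <- q[mask[q] & lab[q] == 0L]
      lab[q] <- cur
      stack <- c(stack, q)
    }
    todo <- which(mask & lab == 0L)
  }
  if (cur <= 1L) return(mask)
  best <- which.max(tabulate(lab[lab > 0L], cur))
  lab == best
}

#' Shape features of a binary mask
#'
#' Computed on the largest connected component: area (mm^2), perimeter (mm,
#' marching-squares subpixel contour), perimeter-area ratio (1/mm),
#' circularity 4*pi*A/P^2, major and minor axis lengths (mm, from second
#' central moments), elongation (major/minor) and solidity (area fraction of
#' the rasterized convex hull).
#'
#' @param mask logical matrix, non-empty.
#' @param spacing pixel spacing in mm.
#' @return Named numeric vector of length 8.
#' @export
shape_features <- function(mask, spacing = 1.0) {
  assert_that(any(mask), "mask is empty")
  mask <- largest_component(mask)
  n <- sum(mask)
  area <- n * spacing^2

  # subpixel perimeter: marching squares at level 0.5 on a zero-padded image;
  # a circular moving average over contour vertices removes the stair-step
  # length bias (raw marching squares overestimates a disk by ~6%)
  pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  cl <- grDevices::contourLines(seq_len(nrow(pad)), seq_len(ncol(pad)),
                                pad, levels = 0.5)
  smooth_closed <- function(v, k = 5L) {
    n <- length(v)
    if (n < k + 2) return(v)
    v <- v[-n]                               # drop duplicated closing vertex
    idx <- outer(seq_len(n - 1), seq_len(k) - (k + 1L) %/% 2L, "+")
    idx <- (idx - 1L) %% (n - 1L) + 1L
    out <- rowMeans(matrix(v[idx], n - 1L, k))
    c(out, out[1])
  }
  per_px <- sum(vapply(cl, function(s) {
    x <- smooth_closed(s$x); y <- smooth_closed(s$y)
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1)))
  perimeter <- per_px * spacing

  idx <- which(mask, arr.ind = TRUE)
  cv <- stats::cov(idx) * (n - 1) / n + diag(1 / 12, 2)  # pixel-area correction
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  major <- 4 * sqrt(ev[1]) * spacing
  minor <- 4 * sqrt(ev[2]) * spacing

  # solidity: pixels inside the convex hull of mask pixel centers
  if (n >= 3) {
    hull <- idx[grDevices::chull(idx[, 1], idx[, 2]), , drop = FALSE]
    bb <- mask_bbox(mask)
    cand <- as.matrix(expand.grid(r = bb$rows, c = bb$cols))
    inside <- rep(TRUE, nrow(cand))
    nh <- nrow(hull)
    for (e in seq_len(nh)) {
      a <- hull[e, ]; b <- hull[e %% nh + 1, ]
      cr <- (b[1] - a[1]) * (cand[, 2] - a[2]) - (b[2] - a[2]) * (cand[, 1] - a[1])
      inside <- inside & cr <= 1e-9
    }
    hull_n <- sum(inside)
    solidity <- if (hull_n > 0) n / hull_n else 1
  } else solidity <- 1

  c(area = area, perimeter = perimeter,
    perimeter_area_ratio = perimeter / area,
    circularity = 4 * pi * area / perimeter^2,
    major_axis = major, minor_axis = minor,
    elongation = if (minor > 0) major / minor else Inf,
    solidity = min(solidity, 1))
}

#' Histogram (first-order) features of ROI intensities
#'
#' Moment and order statistics on the raw intensities; `energy` is the sum of
#' squared intensities; `entropy` (bits) and `uniformity` are computed on the
#' fixed-bin-number discretized histogram. Skewness and excess kurtosis of a
#' constant ROI are 0 by convention.
#'
#' @param img numeric matrix.
#' @param mask logical matrix, non-empty.
#' @param n_bins bins for the entropy/uniformity histogram.
#' @return Named numeric vector of length 14.
#' @export
histogram_features <- function(img, mask, n_bins = 32L) {
  assert_that(any(mask), "mask is empty")
  v <- img[mask]
  m <- mean(v)
  s2 <- mean((v - m)^2)
  s <- sqrt(s2)
  skw <- if (s > 0) mean((v - m)^3) / s^3 else 0
  krt <- if (s > 0) mean((v - m)^4) / s2^2 - 3 else 0
  lab <- discretize(img, mask, n_bins)
  p <- tabulate(lab[!is.na(lab)], attr(lab, "n_bins"))
  p <- p[p > 0] / sum(p)
  c(mean = m, variance = s2, standard_deviation = s, skewness = skw,
    kurtosis = krt, median = stats::median(v), minimum = min(v),
    maximum = max(v), range = diff(range(v)),
    interquartile_range = unname(diff(stats::quantile(v, c(0.25, 0.75)))),
    mean_absolute_deviation = mean(abs(v - m)), energy = sum(v^2),
    entropy = -sum(p * log2(p)), uniformity = sum(p^2))
}

glcm_offsets <- function() list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))

#' Gray-level co-occurrence matrix
#'
#' Symmetric, normalized, averaged over the supplied directions at the given
#' pixel distance. Pairs are counted only when both pixels are inside the ROI.
#'
#' @param lab discretized ROI from [discretize()] (NA outside the ROI).
#' @param distance pixel offset distance (default 1).
#' @param directions list of row/col unit offsets; default the four standard
#'   2D directions (0, 45, 90, 135 degrees).
#' @return n_bins x n_bins matrix summing to 1 (all zeros if the ROI admits
#'   no pixel pair).
#' @export
glcm_matrix <- function(lab, distance = 1L, directions = glcm_offsets()) {
  nb <- attr(lab, "n_bins")
  acc <- matrix(0, nb, nb)
  h <- nrow(lab); w <- ncol(lab)
  for (d in directions) {
    dr <- d[1] * distance; dc <- d[2] * distance
    r1 <- max(1, 1 - dr):min(h, h - dr)
    c1 <- max(1, 1 - dc):min(w, w - dc)
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- matrix(tabulate((a[ok] - 1L) * nb + b[ok], nb * nb), nb, nb,
                  byrow = TRUE)
    g <- tab + t(tab)                      # symmetric
    if (sum(g) > 0) acc <- acc + g / sum(g)
  }
  tot <- sum(acc)
  if (tot > 0) acc / tot else acc
}

#' GLCM texture features
#'
#' Thirteen statistics of the direction-averaged symmetric normalized GLCM.
#' Degenerate conventions: 0*log(0) = 0, and the correlation of a
#' zero-variance gray-level distribution is 1.
#'
#' @param lab discretized ROI (from [discretize()]), or a precomputed GLCM
#'   passed via `glcm`.
#' @param distance,directions forwarded to [glcm_matrix()].
#' @param glcm optional precomputed normalized GLCM.
#' @return Named numeric vector of length 13.
#' @export
glcm_features <- function(lab = NULL, distance = 1L,
                          directions = glcm_offsets(), glcm = NULL) {
  P <- if (is.null(glcm)) glcm_matrix(lab, distance, directions) else glcm
  nb <- nrow(P)
  i <- matrix(seq_len(nb), nb, nb)
  j <- t(i)
  px <- rowSums(P)
  mu_x <- sum(seq_len(nb) * px)
  var_x <- sum((seq_len(nb) - mu_x)^2 * px)
  plog <- function(p) ifelse(p > 0, p * log2(p), 0)
  corr <- if (var_x > 0)
    sum(P * (i - mu_x) * (j - mu_x)) / var_x else 1
  # p_{x+y}
  k <- 2:(2 * nb)
  pxy <- vapply(k, function(s) sum(P[i + j == s]), numeric(1))
  c(contrast = sum(P * (i - j)^2),
    correlation = corr,
    energy = sum(P^2),
    entropy = -sum(plog(P)),
    homogeneity = sum(P / (1 + abs(i - j))),
    homogeneity2 = sum(P / (1 + (i - j)^2)),
    dissimilarity = sum(P * abs(i - j)),
    cluster_shade = sum(P * (i + j - 2 * mu_x)^3),
    cluster_prominence = sum(P * (i + j - 2 * mu_x)^4),
    autocorrelation = sum(P * i * j),
    sum_average = sum(k * pxy),
    sum_entropy = -sum(plog(pxy)),
    maximum_probability = max(P))
}

glrlm_offsets <- function() list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))

# Run-length counts for one direction: maximal runs of equal gray level along
# the direction's lines, broken by out-of-ROI pixels.
glrlm_matrix_dir <- function(lab, d) {
  nb <- attr(lab, "n_bins")
  h <- nrow(lab); w <- ncol(lab)
  lines <- if (identical(d, c(0, 1))) {
    split(as.vector(t(lab)), rep(seq_len(h), each = w))
  } else if (identical(d, c(-1, 0))) {
    split(as.vector(lab), rep(seq_len(w), each = h))
  } else {
    ii <- matrix(seq_len(h), h, w); jj <- t(matrix(seq_len(w), w, h))
    key <- if (identical(d, c(-1, 1))) ii + jj else ii - jj
    split(as.vector(lab), as.vector(key))
  }
  maxlen <- max(h, w)
  R <- matrix(0, nb, maxlen)
  for (ln in lines) {
    r <- rle(ln)
    keep <- !is.na(r$values)
    if (!any(keep)) next
    for (q in which(keep))
      R[r$values[q], r$lengths[q]] <- R[r$values[q], r$lengths[q]] + 1
  }
  R
}

#' GLRLM texture features
#'
#' Eight run-length statistics computed per direction and averaged over the
#' four standard directions. `LRHGLE` is the low-run (short-run) high
#' gray-level emphasis, sum of r(i,l) * i^2 / l^2 over runs.
#'
#' @param lab discretized ROI from [discretize()].
#' @param directions list of row/col offsets (default 0/45/90/135 degrees).
#' @return Named numeric vector of length 8.
#' @export
glrlm_features <- function(lab, directions = glrlm_offsets()) {
  assert_that(any(!is.na(lab)), "empty ROI")
  np <- sum(!is.na(lab))
  per_dir <- vapply(directions, function(d) {
    R <- glrlm_matrix_dir(lab, d)
    nr <- sum(R)
    i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
    l <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
    c(SRE = sum(R / l^2) / nr,
      LRE = sum(R * l^2) / nr,
      GLN = sum(rowSums(R)^2) / nr,
      RLN = sum(colSums(R)^2) / nr,
      RP = nr / np,
      LGRE = sum(R / i^2) / nr,
      HGRE = sum(R * i^2) / nr,
      LRHGLE = sum(R * i^2 / l^2) / nr)
  }, numeric(8))
  rowMeans(per_dir)
}

#' Differential box-counting fractal dimension of the ROI intensity surface
#'
#' Shift-invariant differential box counting over box sizes 2, 4, 8, 16: each
#' s x s box contributes `ceil((max - min) / h_s) + 1` stacked boxes with
#' column height `h_s = s * G / M` (G = in-ROI intensity range, M = shorter
#' bounding-box side). The dimension is the least-squares slope of
#' log(count) against log(1/s); a flat surface yields 2.
#'
#' @param img numeric matrix.
#' @param mask logical matrix; bounding box must be at least 8 x 8.
#' @param box_sizes box edge lengths in pixels.
#' @return Single numeric value (the dimension).
#' @export
fractal_feature <- function(img, mask, box_sizes = c(2L, 4L, 8L, 16L)) {
  assert_that(any(mask), "mask is empty")
  bb <- mask_bbox(mask)
  assert_that(length(bb$rows) >= 8 && length(bb$cols) >= 8,
              "ROI bounding box must be at least 8x8")
  v <- img[bb$rows, bb$cols, drop = FALSE]
  m <- mask[bb$rows, bb$cols, drop = FALSE]
  v[!m] <- mean(v[m])                      # neutral fill outside the ROI
  G <- diff(range(v)); M <- min(dim(v))
  counts <- vapply(box_sizes, function(s) {
    ri <- ceiling(seq_len(nrow(v)) / s)
    ci <- ceiling(seq_len(ncol(v)) / s)
    grp <- interaction(ri[row(v)], ci[col(v)], drop = TRUE)
    mx <- tapply(v, grp, max); mn <- tapply(v, grp, min)
    if (G <= 0) return(length(mx))
    h <- s * G / M
    sum(ceiling((mx - mn) / h) + 1)
  }, numeric(1))
  unname(stats::coef(stats::lm(log(counts) ~ log(1 / box_sizes)))[2])
}

#' Extract the 116 handcrafted features for one ROI
#'
#' Shape features are computed once from the mask; histogram, GLCM, GLRLM and
#' fractal features are computed per image variant X, XL, XH. Any family that
#' errors on a degenerate input yields `NaN` for its features, recorded in the
#' `validity` attribute.
#'
#' @param study a `preprocessed_study` from [make_variants()] or
#'   [preprocess_case()].
#' @param mask logical ROI matrix on the study grid.
#' @param n_bins gray levels for discretization (default 32).
#' @param glcm_distance GLCM pixel distance (default 1).
#' @return Named numeric vector of length 116 in [feature_catalog()] order,
#'   with attribute `validity`.
#' @export
extract_handcrafted <- function(study, mask, n_bins = 32L, glcm_distance = 1L) {
  stopifnot(inherits(study, "preprocessed_study"))
  assert_that(any(mask), "mask is empty")
  cat_df <- feature_catalog()
  out <- stats::setNames(rep(NA_real_, nrow(cat_df)), cat_df$name)
  validity <- character(0)
  safely <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      validity <<- c(validity, paste0(tag, ": ", conditionMessage(e)))
      NULL
    })
  }
  sh <- safely("shape", shape_features(mask, study$pixel_spacing))
  if (!is.null(sh)) out[paste0("Shape_", SHAPE_STATS)] <- sh
  for (v in c("X", "XL", "XH")) {
    img <- study[[v]]
    hs <- safely(paste0(v, "_H"), histogram_features(img, mask, n_bins))
    if (!is.null(hs)) out[paste0(v, "_H_", HIST_STATS)] <- hs
    lab <- safely(paste0(v, "_discretize"), discretize(img, mask, n_bins))
    if (!is.null(lab)) {
      gf <- safely(paste0(v, "_GLCM"), glcm_features(lab, glcm_distance))
      if (!is.null(gf)) out[paste0(v, "_GLCM_", GLCM_STATS)] <- gf
      rf <- safely(paste0(v, "_GLRLM"), glrlm_features(lab))
      if (!is.null(rf)) out[paste0(v, "_GLRLM_", GLRLM_STATS)] <- rf
    }
    fd <- safely(paste0(v, "_F"), fractal_feature(img, mask))
    if (!is.null(fd)) out[paste0(v, "_F_dimension")] <- fd
  }
  attr(out, "validity") <- validity
  out
}
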