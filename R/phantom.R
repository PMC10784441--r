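# Synthetic non-contrast CT phantom cohort: an elliptical kidney embedded in a
# perirenal fat annulus inside a soft-tissue body, on a HU scale. The generator
# plants per-case texture-heterogeneity effects whose link to the binary
# treatment-benefit label is exactly logistic, so recovery of the planted
# effects by the downstream pipeline can be tested.

#' Specification of a synthetic CT slice phantom
#'
#' Describes the geometry, tissue intensities (HU) and texture heterogeneity of
#' a single synthetic axial slice: a soft-tissue body ellipse containing an
#' elliptical kidney surrounded by a hypodense perirenal fat annulus.
#'
#' @param image_size integer vector of length 2, image size in pixels.
#' @param pixel_spacing pixel spacing in mm (isotropic).
#' @param body_hu,kidney_hu,fat_hu mean tissue intensities in Hounsfield units.
#'   Fat must be hypodense relative to soft tissue (`fat_hu < body_hu`).
#' @param kidney_texture_sd,fat_texture_sd within-tissue intensity SD in HU; the
#'   heterogeneity knobs used to plant recoverable effects.
#' @param noise_sd global acquisition noise SD in HU, added everywhere.
#' @param kidney_radii semi-axes of the kidney ellipse in pixels.
#' @param fat_ring_width width of the perirenal fat annulus in pixels.
#' @param seed integer seed; the same seed reproduces the slice bit-exactly.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(256L, 256L), pixel_spacing = 1.0,
                         body_hu = 40, kidney_hu = 32, fat_hu = -90,
                         kidney_texture_sd = 8, fat_texture_sd = 10,
                         noise_sd = 4, kidney_radii = NULL,
                         fat_ring_width = NULL, seed = 1L) {
  image_size <- as.integer(image_size)
  assert_that(length(image_size) == 2 && all(image_size >= 32),
              "image_size must be two integers >= 32")
  assert_that(pixel_spacing > 0, "pixel_spacing must be positive")
  assert_that(fat_hu < body_hu, "fat must be hypodense: fat_hu < body_hu")
  assert_that(kidney_texture_sd >= 0 && fat_texture_sd >= 0 && noise_sd >= 0,
              "texture/noise SDs must be non-negative")
  if (is.null(kidney_radii)) kidney_radii <- round(image_size * c(0.18, 0.13))
  if (is.null(fat_ring_width)) fat_ring_width <- max(4, round(min(image_size) * 0.06))
  # annulus must fit inside the body ellipse, which fills 90% of the canvas
  if (any(kidney_radii + fat_ring_width > 0.40 * image_size))
    stopf("kidney ellipse plus fat ring does not fit the canvas")
  structure(list(image_size = image_size, pixel_spacing = pixel_spacing,
                 body_hu = body_hu, kidney_hu = kidney_hu, fat_hu = fat_hu,
                 kidney_texture_sd = kidney_texture_sd,
                 fat_texture_sd = fat_texture_sd, noise_sd = noise_sd,
                 kidney_radii = as.numeric(kidney_radii),
                 fat_ring_width = as.numeric(fat_ring_width),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one synthetic CT slice with kidney and perirenal fat masks
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (HU matrix), `roi1` (kidney mask, logical
#'   matrix), `roi2` (perirenal fat mask, disjoint from `roi1`),
#'   `pixel_spacing`, and the generating `spec`.
#' @export
generate_slice <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  # kidney is offset from the body centre, as on an axial abdominal slice
  ky <- cy + 0.05 * h; kx <- cx - 0.08 * w
  a <- spec$kidney_radii[2]; b <- spec$kidney_radii[1]   # x, y semi-axes
  r2_kid <- ((xx - kx) / a)^2 + ((yy - ky) / b)^2
  ring <- spec$fat_ring_width
  r2_fat <- ((xx - kx) / (a + ring))^2 + ((yy - ky) / (b + ring))^2
  r2_body <- ((xx - cx) / (0.45 * w))^2 + ((yy - cy) / (0.45 * h))^2

  roi1 <- r2_kid <= 1
  roi2 <- (r2_fat <= 1) & !roi1
  body <- r2_body <= 1

  with_seed(spec$seed, {
    img <- matrix(-1000, h, w)                       # air
    img[body] <- spec$body_hu
    img[roi2] <- spec$fat_hu
    img[roi1] <- spec$kidney_hu
    if (spec$kidney_texture_sd > 0)
      img[roi1] <- img[roi1] + stats::rnorm(sum(roi1), 0, spec$kidney_texture_sd)
    if (spec$fat_texture_sd > 0)
      img[roi2] <- img[roi2] + stats::rnorm(sum(roi2), 0, spec$fat_texture_sd)
    if (spec$noise_sd > 0)
      img[body] <- img[body] + stats::rnorm(sum(body), 0, spec$noise_sd)
    list(image = img, roi1 = roi1, roi2 = roi2,
         pixel_spacing = spec$pixel_spacing, spec = spec)
  })
}

#' Classify a post-treatment renal-function outcome
#'
#' Applies the eGFR-based benefit rule: improvement is a relative eGFR increase
#' of at least 20% from the pre-treatment level sustained for at least 3
#' months; a decrease of at least 20% is exacerbation; anything in between is
#' stable. Only improvement counts as benefit. Thresholds are inclusive.
#'
#' @param pre,post pre- and post-treatment eGFR in ml/min/1.73m^2.
#' @param months follow-up duration in months. Below 3 months the persistence
#'   requirement cannot be assessed and the outcome is `"undetermined"` with an
#'   `NA` label, never silently non-benefit.
#' @param case_id optional case identifier carried through.
#' @return A one-row data.frame with `case_id`, `pre_eGFR`, `post_eGFR`,
#'   `followup_months`, `category` (improvement/stable/exacerbation/
#'   undetermined) and `label` (benefit/non-benefit or NA).
#' @export
classify_outcome <- function(pre, post, months, case_id = NA_character_) {
  assert_that(is.numeric(pre) && pre > 0, "pre-treatment eGFR must be positive")
  assert_that(is.numeric(months) && months >= 0, "months must be non-negative")
  rel <- (post - pre) / pre
  if (months < 3) {
    category <- "undetermined"; label <- NA_character_
  } else if (rel >= 0.20) {
    category <- "improvement"; label <- "benefit"
  } else if (rel <= -0.20) {
    category <- "exacerbation"; label <- "non-benefit"
  } else {
    category <- "stable"; label <- "non-benefit"
  }
  data.frame(case_id = case_id, pre_eGFR = pre, post_eGFR = post,
             followup_months = months, category = category, label = label,
             stringsAsFactors = FALSE)
}

#' Specification of a patch degradation
#'
#' Exactly five kinds are defined, matching the five-class pretext task:
#' `normal` (identity), `blur` (Gaussian, magnitude = sigma in px), `noise`
#' (additive Gaussian, magnitude = SD in HU), `distort` (elastic deformation,
#' magnitude = displacement amplitude in px) and `shift` (translation with
#' reflection padding, magnitude = displacement in px).
#'
#' @param kind one of `"normal"`, `"blur"`, `"noise"`, `"distort"`, `"shift"`.
#' @param magnitude kind-specific strength; must be positive for every
#'   non-`normal` kind (an identity degradation would leak the label).
#' @param seed integer seed for the stochastic kinds.
#' @export
degradation_spec <- function(kind, magnitude = NULL, seed = 1L) {
  kinds <- degradation_kinds()
  kind <- match.arg(kind, kinds)
  if (is.null(magnitude))
    magnitude <- switch(kind, normal = 0, blur = 2, noise = 20, distort = 4, shift = 12)
  if (kind != "normal" && magnitude <= 0)
    stopf("degradation '%s' requires a positive magnitude", kind)
  structure(list(kind = kind, magnitude = magnitude, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' The five degradation kinds of the pretext task
#' @export
degradation_kinds <- function() c("normal", "blur", "noise", "distort", "shift")

#' Apply a degradation to a 64x64 patch
#'
#' @param patch a 64x64 numeric matrix.
#' @param d a [degradation_spec()].
#' @return The degraded 64x64 matrix; `kind = "normal"` returns the input
#'   unchanged.
#' @export
degrade_patch <- function(patch, d) {
  stopifnot(inherits(d, "degradation_spec"))
  assert_that(is.matrix(patch) && all(dim(patch) == c(64, 64)),
              "patch must be a 64x64 matrix")
  switch(d$kind,
    normal = patch,
    blur = gaussian_smooth(patch, d$magnitude),
    noise = with_seed(d$seed,
      patch + matrix(stats::rnorm(length(patch), 0, d$magnitude), nrow(patch))),
    distort = with_seed(d$seed, elastic_distort(patch, d$magnitude)),
    shift = with_seed(d$seed, {
      theta <- stats::runif(1, 0, 2 * pi)
      translate_patch(patch, round(d$magnitude * cos(theta)),
                      round(d$magnitude * sin(theta)))
    })
  )
}

#' Translate an image by whole pixels with reflection padding
#'
#' @param img numeric matrix.
#' @param dx,dy signed column/row displacement in pixels.
#' @export
translate_patch <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  reflect <- function(idx, n) {
    # reflect indices into 1..n (mirror boundary without repeating the edge)
    idx <- (idx - 1) %% (2 * n - 2)
    ifelse(idx < n, idx + 1, 2 * n - idx - 1)
  }
  rows <- reflect(seq_len(h) - round(dy), h)
  cols <- reflect(seq_len(w) - round(dx), w)
  img[rows, cols, drop = FALSE]
}

# Smooth random displacement field, bilinear resampling with edge clamping.
elastic_distort <- function(img, amplitude, field_sigma = 8) {
  h <- nrow(img); w <- ncol(img)
  smooth_field <- function() {
    f <- gaussian_smooth(matrix(stats::rnorm(h * w), h, w), field_sigma)
    f <- f - mean(f)
    s <- stats::sd(f)
    if (s < .Machine$double.eps) matrix(0, h, w) else f * (amplitude / s)
  }
  dy <- smooth_field(); dx <- smooth_field()
  yy <- matrix(seq_len(h), h, w) + dy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) + dx
  bilinear_sample(img, yy, xx)
}

# Bilinear interpolation at (possibly fractional) coordinates, edge-clamped.
# Output has the shape of the coordinate grids yy/xx.
bilinear_sample <- function(img, yy, xx) {
  h <- nrow(img); w <- ncol(img)
  out_dim <- dim(yy)
  yy <- pmin(pmax(yy, 1), h); xx <- pmin(pmax(xx, 1), w)
  y0 <- pmin(floor(yy), h - 1); x0 <- pmin(floor(xx), w - 1)
  fy <- yy - y0; fx <- xx - x0
  y0v <- as.vector(y0); x0v <- as.vector(x0)
  v <- (1 - fy) * (1 - fx) * img[cbind(y0v, x0v)] +
       (1 - fy) * fx       * img[cbind(y0v, x0v + 1L)] +
       fy       * (1 - fx) * img[cbind(y0v + 1L, x0v)] +
       fy       * fx       * img[cbind(y0v + 1L, x0v + 1L)]
  matrix(v, out_dim[1], out_dim[2])
}

# Separable Gaussian smoothing with reflected boundaries.
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) {       # along rows (first dim)
    n <- nrow(m)
    pad <- rbind(m[rev(seq_len(min(r, n - 1)) + 1), , drop = FALSE],
                 m,
                 m[rev(n - seq_len(min(r, n - 1))), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(img))))
}

#' Build an outcome-labeled synthetic cohort with planted texture effects
#'
#' Generates `n` phantom cases whose per-case texture heterogeneity carries the
#' planted effects. Latent effect variables are drawn from equal-variance
#' Gaussian class conditionals (mean +beta/2 in the benefit class, -beta/2
#' otherwise), so the label probability given the latents is exactly logistic
#' with slope `beta` for each planted effect; the coefficients are recorded in
#' `effect_model`. The latent value modulates the corresponding texture SD
#' multiplicatively. eGFR trajectories are generated consistently with each
#' case's label and verified through [classify_outcome()].
#'
#' @param n cohort size (default 52).
#' @param n_benefit number of benefit cases (default 18, so 18/34).
#' @param effect_sizes named numeric vector of logistic slopes for the planted
#'   effects; recognized names are `fat` (perirenal fat texture) and `kidney`
#'   (renal texture). All-zero slopes are allowed and flagged as a null cohort.
#' @param base_spec a [phantom_spec()] providing geometry and baseline HU.
#' @param texture_log_scale multiplicative modulation strength: texture SD is
#'   `base * exp(texture_log_scale * latent)`.
#' @param seed integer seed; cohorts are reproducible bit-exactly.
#' @return An object of class `synthetic_cohort`: `cases` (list of slices with
#'   masks), `outcomes` (data.frame), `labels` (factor, benefit level last),
#'   `effect_model` (coefficients), `ground_truth` (per-case latents and
#'   texture SDs), `null_cohort` flag and counts.
#' @export
build_cohort <- function(n = 52L, n_benefit = 18L,
                         effect_sizes = c(fat = 2.0, kidney = 1.2),
                         base_spec = phantom_spec(), texture_log_scale = 0.25,
                         seed = 1L) {
  assert_that(n_benefit > 0 && n_benefit < n, "need 0 < n_benefit < n")
  null_cohort <- all(effect_sizes == 0)
  b_fat <- if ("fat" %in% names(effect_sizes)) effect_sizes[["fat"]] else 0
  b_kid <- if ("kidney" %in% names(effect_sizes)) effect_sizes[["kidney"]] else 0

  with_seed(derive_seed(seed, 1L), {
    lab <- sample(rep(c("benefit", "non-benefit"), c(n_benefit, n - n_benefit)))
    sgn <- ifelse(lab == "benefit", 0.5, -0.5)
    u_fat <- stats::rnorm(n, mean = sgn * b_fat)
    u_kid <- stats::rnorm(n, mean = sgn * b_kid)
    fat_sd <- base_spec$fat_texture_sd * exp(texture_log_scale * u_fat)
    kid_sd <- base_spec$kidney_texture_sd * exp(texture_log_scale * u_kid)

    pre <- pmax(15, ifelse(lab == "benefit", stats::rnorm(n, 77.8, 31.4),
                           stats::rnorm(n, 63.8, 26.7)))
    months <- pmax(3, exp(stats::rnorm(n, log(3.7), 0.25)))
    rel <- numeric(n)
    ben <- lab == "benefit"
    rel[ben] <- 0.20 + stats::rexp(sum(ben), rate = 1 / 0.15)
    exac <- !ben & stats::runif(n) < 0.2
    rel[exac] <- -0.20 - stats::rexp(sum(exac), rate = 1 / 0.10)
    stab <- !ben & !exac
    rel[stab] <- stats::runif(sum(stab), -0.195, 0.195)
    post <- pre * (1 + rel)
    ids <- sprintf("case_%03d", seq_len(n))

    outcomes <- do.call(rbind, lapply(seq_len(n), function(i)
      classify_outcome(pre[i], post[i], months[i], case_id = ids[i])))
    stopifnot(identical(outcomes$label, lab))   # generation is label-consistent

    cases <- lapply(seq_len(n), function(i) {
      sp <- base_spec
      sp$fat_texture_sd <- fat_sd[i]
      sp$kidney_texture_sd <- kid_sd[i]
      sp$seed <- derive_seed(seed, 100L + i)
      generate_slice(sp)
    })
    names(cases) <- ids

    structure(list(
      cases = cases, outcomes = outcomes,
      labels = factor(lab, levels = c("non-benefit", "benefit")),
      effect_model = c(intercept = log(n_benefit / (n - n_benefit)),
                       fat = b_fat, kidney = b_kid),
      ground_truth = data.frame(case_id = ids, u_fat = u_fat, u_kid = u_kid,
                                fat_texture_sd = fat_sd,
                                kidney_texture_sd = kid_sd,
                                stringsAsFactors = FALSE),
      null_cohort = null_cohort,
      n_benefit = sum(lab == "benefit"), n_nonbenefit = sum(lab != "benefit"),
      seed = seed),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d cases (%d benefit / %d non-benefit)%s\n",
              length(x$cases), x$n_benefit, x$n_nonbenefit,
              if (x$null_cohort) " [null cohort: no planted effect]" else ""))
  cat(sprintf("  planted logistic slopes: fat = %.3g, kidney = %.3g\n",
              x$effect_model[["fat"]], x$effect_model[["kidney"]]))
  invisible(x)
}

#' Build a labeled degradation-patch dataset for pretext training
#'
#' Samples 64x64 patches of body tissue from synthetic patients, degrades each
#' with one uniformly drawn kind, and assigns a patient-grouped 7:1:2
#' train/validation/test split (no patient spans two partitions).
#'
#' @param n_patients number of synthetic source patients.
#' @param patches_per_patient patches sampled per patient.
#' @param base_spec [phantom_spec()] for the source slices.
#' @param magnitudes named list of magnitude ranges per kind, each `c(lo, hi)`.
#'   Defaults: blur sigma 1-3 px, noise SD 10-30 HU, elastic amplitude 2-6 px,
#'   translation 8-16 px.
#' @param seed integer seed.
#' @return A list with `x` (array 64 x 64 x n), `y` (factor over the five
#'   kinds), `patient` (ids), `split` (train/val/test).
#' @export
build_pretext_dataset <- function(n_patients = 25L, patches_per_patient = 20L,
                                  base_spec = phantom_spec(image_size = c(128L, 128L)),
                                  magnitudes = list(blur = c(1, 3), noise = c(10, 30),
                                                    distort = c(2, 6), shift = c(8, 16)),
                                  seed = 1L) {
  kinds <- degradation_kinds()
  n <- n_patients * patches_per_patient
  x <- array(0, c(64, 64, n))
  y <- character(n); patient <- character(n)
  with_seed(derive_seed(seed, 2L), {
    # patient-grouped split 7:1:2
    sh <- sample(n_patients)
    n_tr <- max(1L, round(0.7 * n_patients))
    n_va <- max(1L, round(0.1 * n_patients))
    split_of <- rep("test", n_patients)
    split_of[sh[seq_len(n_tr)]] <- "train"
    split_of[sh[n_tr + seq_len(min(n_va, n_patients - n_tr - 1))]] <- "val"
    idx <- 0L
    for (p in seq_len(n_patients)) {
      sp <- base_spec
      sp$seed <- derive_seed(seed, 500L + p)
      sl <- generate_slice(sp)
      h <- nrow(sl$image); w <- ncol(sl$image)
      body_rows <- round(h * 0.2):round(h * 0.8 - 64)
      body_cols <- round(w * 0.2):round(w * 0.8 - 64)
      for (q in seq_len(patches_per_patient)) {
        idx <- idx + 1L
        r0 <- sample(body_rows, 1); c0 <- sample(body_cols, 1)
        patch <- sl$image[r0 + 0:63, c0 + 0:63]
        kind <- sample(kinds, 1)
        mag <- if (kind == "normal") 0 else stats::runif(1, magnitudes[[kind]][1],
                                                         magnitudes[[kind]][2])
        d <- degradation_spec(kind, if (kind == "normal") NULL else mag,
                              seed = derive_seed(seed, 10000L + idx))
        x[, , idx] <- degrade_patch(patch, d)
        y[idx] <- kind
        patient[idx] <- sprintf("pt_%03d", p)
      }
    }
    list(x = x, y = factor(y, levels = kinds), patient = patient,
         split = split_of[as.integer(sub("pt_", "", patient))])
  })
}

#' Write a synthetic cohort to disk as NIfTI images plus a CSV outcome table
#'
#' @param cohort a [build_cohort()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the path to the outcome CSV.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- cohort$cases[[1]]$pixel_spacing
  as_nifti <- function(m) {
    im <- RNifti::asNifti(m)
    RNifti::pixdim(im) <- c(sp, sp)
    im
  }
  for (id in names(cohort$cases)) {
    cs <- cohort$cases[[id]]
    RNifti::writeNifti(as_nifti(cs$image),
                       file.path(dir, paste0(id, "_image.nii.gz")))
    RNifti::writeNifti(as_nifti(cs$roi1 * 1L),
                       file.path(dir, paste0(id, "_roi1.nii.gz")))
    RNifti::writeNifti(as_nifti(cs$roi2 * 1L),
                       file.path(dir, paste0(id, "_roi2.nii.gz")))
  }
  csv <- file.path(dir, "outcomes.csv")
  utils::write.csv(cohort$outcomes, csv, row.names = FALSE)
  invisible(csv)
}
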