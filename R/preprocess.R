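# Standardization of a CT slice before feature extraction: gray-level
# histogram alignment to decile landmarks, resampling to a common pixel size,
# and construction of the image triple X (original), XL (Gaussian-smoothed),
# XH = X - XL (detail residual: boundaries, streaks, plaques).

#' Decile landmark set of one or more images
#'
#' Pools the supplied images and returns their intensity deciles (0%, 10%,
#' ..., 100%), the reference used by [align_histogram()].
#'
#' @param imgs a matrix or list of matrices.
#' @param masks optional list of logical masks restricting the pooled pixels.
#' @return Numeric vector of length 11, non-decreasing.
#' @export
reference_landmarks <- function(imgs, masks = NULL) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  px <- unlist(lapply(seq_along(imgs), function(i) {
    v <- imgs[[i]]
    if (!is.null(masks)) v[masks[[i]]] else as.vector(v)
  }))
  stats::quantile(px, probs = seq(0, 1, 0.1), names = FALSE)
}

#' Align an image's gray-level histogram to reference decile landmarks
#'
#' Matches the image's own deciles to the reference deciles by a piecewise
#' linear map, extended linearly beyond the outermost landmarks. The map is
#' monotone, so pixel intensity ranks are preserved.
#'
#' @param img numeric matrix (HU).
#' @param reference numeric vector of 11 non-decreasing landmark intensities.
#' @return The remapped image. A constant image has no defined map and is
#'   returned unchanged with a warning.
#' @export
align_histogram <- function(img, reference) {
  assert_that(length(reference) == 11 && !is.unsorted(reference),
              "reference must be 11 non-decreasing decile landmarks")
  own <- stats::quantile(img, probs = seq(0, 1, 0.1), names = FALSE)
  if (diff(range(own)) < .Machine$double.eps) {
    warning("constant image: histogram alignment undefined, returning input")
    return(img)
  }
  keep <- c(TRUE, diff(own) > 0)          # collapse tied landmarks
  out <- stats::approx(own[keep], reference[keep], xout = as.vector(img),
                       rule = 2)$y
  matrix(out, nrow(img), ncol(img))
}

#' Resample an image to a target pixel spacing
#'
#' Intensities are interpolated with a separable natural cubic spline (exact
#' on constant and linear images); binary masks must use `method =
#' "nearest"` so they stay binary. Pixel-center convention throughout.
#'
#' @param img numeric (or logical, for masks) matrix.
#' @param spacing current pixel spacing in mm.
#' @param target_spacing desired pixel spacing in mm (default 0.5).
#' @param method `"cubic"` (intensity images) or `"nearest"` (masks).
#' @param max_pixels guard against accidental huge outputs.
#' @return A list with `image` and `pixel_spacing`.
#' @export
resample_image <- function(img, spacing, target_spacing = 0.5,
                           method = c("cubic", "nearest"),
                           max_pixels = 4096L^2) {
  method <- match.arg(method)
  assert_that(target_spacing > 0, "target_spacing must be positive")
  was_logical <- is.logical(img)
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  h <- nrow(img); w <- ncol(img)
  h2 <- max(1L, round(h * spacing / target_spacing))
  w2 <- max(1L, round(w * spacing / target_spacing))
  if (as.double(h2) * w2 > max_pixels)
    stopf("resampled size %dx%d exceeds the configured pixel cap", h2, w2)
  # output pixel centers mapped into input index space (pixel-center convention)
  ry <- pmin(pmax(((seq_len(h2) - 0.5) * target_spacing / spacing) + 0.5, 1), h)
  rx <- pmin(pmax(((seq_len(w2) - 0.5) * target_spacing / spacing) + 0.5, 1), w)
  if (method == "nearest") {
    out <- img[round(ry), round(rx), drop = FALSE]
  } else {
    # separable: spline along rows, then along columns
    tmp <- apply(img, 2, function(col)
      stats::splinefun(seq_len(h), col, method = "natural")(ry))
    tmp <- matrix(tmp, length(ry), w)
    out <- t(apply(tmp, 1, function(row)
      stats::splinefun(seq_len(w), row, method = "natural")(rx)))
    out <- matrix(out, length(ry), length(rx))
  }
  if (was_logical) out <- out > 0.5
  list(image = out, pixel_spacing = target_spacing)
}

#' Build the X / XL / XH image triple
#'
#' `XL` is the Gaussian-smoothed image and `XH = X - XL` is the complementary
#' detail residual, so `X = XL + XH` holds pixelwise by construction. Adding a
#' constant to `X` shifts `XL` by the same constant and leaves `XH` unchanged.
#'
#' @param img standardized CT slice (numeric matrix).
#' @param sigma_smooth Gaussian sigma in pixels (default 1.5, on the
#'   resampled 0.5 mm grid).
#' @param pixel_spacing pixel spacing in mm, carried through.
#' @param params optional provenance (reference id, resampling method).
#' @return An object of class `preprocessed_study` with elements `X`, `XL`,
#'   `XH`, `pixel_spacing` and `params`.
#' @export
make_variants <- function(img, sigma_smooth = 1.5, pixel_spacing = 0.5,
                          params = list()) {
  assert_that(sigma_smooth > 0, "sigma_smooth must be positive")
  XL <- gaussian_smooth(img, sigma_smooth)
  structure(list(X = img, XL = XL, XH = img - XL,
                 pixel_spacing = pixel_spacing,
                 params = c(params, list(sigma_smooth = sigma_smooth))),
            class = "preprocessed_study")
}

#' Standardize one phantom or loaded case end to end
#'
#' Optional histogram alignment, cubic resampling of the image with
#' nearest-neighbor resampling of both masks to the target spacing, then the
#' X/XL/XH triple.
#'
#' @param slice a list with `image`, `roi1`, `roi2`, `pixel_spacing` (as
#'   produced by [generate_slice()] or [read_ct_case()]).
#' @param reference optional decile landmarks for [align_histogram()].
#' @param target_spacing resampling target in mm.
#' @param sigma_smooth smoothing sigma in pixels.
#' @return A `preprocessed_study` that also carries `roi1` and `roi2` on the
#'   resampled grid.
#' @export
preprocess_case <- function(slice, reference = NULL, target_spacing = 0.5,
                            sigma_smooth = 1.5) {
  img <- slice$image
  if (!is.null(reference)) img <- align_histogram(img, reference)
  if (!isTRUE(all.equal(slice$pixel_spacing, target_spacing))) {
    img <- resample_image(img, slice$pixel_spacing, target_spacing, "cubic")$image
    roi1 <- resample_image(slice$roi1, slice$pixel_spacing, target_spacing, "nearest")$image
    roi2 <- resample_image(slice$roi2, slice$pixel_spacing, target_spacing, "nearest")$image
  } else {
    roi1 <- slice$roi1; roi2 <- slice$roi2
  }
  st <- make_variants(img, sigma_smooth, target_spacing,
                      params = list(resampling = "natural-cubic",
                                    aligned = !is.null(reference)))
  st$roi1 <- roi1 > 0.5
  st$roi2 <- roi2 > 0.5
  st
}

#' Read a CT case (image plus masks) from NIfTI files
#'
#' @param image_path NIfTI image path; HU values expected.
#' @param roi1_path,roi2_path NIfTI mask paths (nonzero = inside).
#' @return A list with `image`, `roi1`, `roi2`, `pixel_spacing`, suitable for
#'   [preprocess_case()].
#' @export
read_ct_case <- function(image_path, roi1_path, roi2_path) {
  im <- RNifti::readNifti(image_path)
  sp <- RNifti::pixdim(im)[1]
  as_mat <- function(x) matrix(as.numeric(x), dim(x)[1], dim(x)[2])
  list(image = as_mat(im),
       roi1 = as_mat(RNifti::readNifti(roi1_path)) > 0,
       roi2 = as_mat(RNifti::readNifti(roi2_path)) > 0,
       pixel_spacing = sp)
}
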