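#' Two-channel image pair
#'
#' Matched rasters of a junction marker (channel A, e.g. beta-catenin)
#' and F-actin (channel B, e.g. phalloidin), as non-negative numeric
#' matrices of identical dimension, at least 64 x 64 pixels for stable
#' correlation statistics.
#'
#' @param channel_a,channel_b Numeric matrices, same dimensions.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(channel_a, channel_b) {
  channel_a <- as_intensity_matrix(channel_a, "channel_a")
  channel_b <- as_intensity_matrix(channel_b, "channel_b")
  if (!identical(dim(channel_a), dim(channel_b))) {
    stop("channels must have identical dimensions", call. = FALSE)
  }
  if (any(dim(channel_a) < 64)) {
    stop("images must be at least 64 x 64 pixels", call. = FALSE)
  }
  structure(list(channel_a = channel_a, channel_b = channel_b),
            class = "image_pair")
}

as_intensity_matrix <- function(x, what) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", what),
                           call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and non-negative", what),
         call. = FALSE)
  }
  x
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("Image pair: %d x %d pixels\n",
              nrow(x$channel_a), ncol(x$channel_a)))
  invisible(x)
}

#' Threshold segmentation of an intensity image
#'
#' Binarises an image as intensity > threshold, with the threshold
#' either chosen by Otsu's method over the image's own intensity range
#' or supplied as a fixed value. The threshold used is attached as
#' attribute `"threshold"`.
#'
#' @param image Numeric matrix (or `image_pair` channel).
#' @param method `"otsu"` or `"fixed"`.
#' @param value Threshold for `method = "fixed"`.
#' @return Logical matrix with attribute `"threshold"`.
#' @export
threshold_segment <- function(image, method = c("otsu", "fixed"),
                              value = NULL) {
  method <- match.arg(method)
  image <- as_intensity_matrix(image, "image")
  if (method == "otsu") {
    rng <- range(image)
    if (rng[1] == rng[2]) {
      stop("degenerate image: constant intensity, Otsu undefined",
           call. = FALSE)
    }
    th <- EBImage::otsu(EBImage::Image(image), range = rng, levels = 256)
  } else {
    if (is.null(value)) stop("'value' required for fixed thresholding",
                             call. = FALSE)
    th <- value
  }
  mask <- image > th
  attr(mask, "threshold") <- as.numeric(th)
  mask
}

#' Colocalization correlation coefficient
#'
#' Pearson correlation between the two channels after threshold
#' segmentation. The default (`method = "mask"`) correlates the binary
#' masks over all pixels, which for binary data equals the phi
#' coefficient of the 2x2 pixel contingency table: 0 for independent
#' channels, 1 for perfect overlap. `method = "intensity"` instead
#' correlates raw intensities restricted to the union of the two masks.
#' Which variant the original plugin-style analyses used is not always
#' documented, so both are provided; when they disagree by more than
#' 0.1 the alternative value is attached as attribute `"cc_other"`.
#'
#' @param pair An [image_pair()].
#' @param method `"mask"` (default) or `"intensity"`.
#' @param threshold_method,threshold_a,threshold_b Thresholding control:
#'   Otsu by default, or fixed per-channel values.
#' @return Correlation coefficient in \[-1, 1\], with attributes
#'   `"method"`, `"threshold_a"`, `"threshold_b"` (and `"cc_other"`
#'   when the two variants disagree by > 0.1).
#' @export
correlation_coefficient <- function(pair,
                                    method = c("mask", "intensity"),
                                    threshold_method = c("otsu", "fixed"),
                                    threshold_a = NULL,
                                    threshold_b = NULL) {
  stopifnot(inherits(pair, "image_pair"))
  method <- match.arg(method)
  threshold_method <- match.arg(threshold_method)
  seg <- function(img, value, which) {
    m <- if (threshold_method == "otsu") {
      threshold_segment(img, "otsu")
    } else {
      threshold_segment(img, "fixed", value = value)
    }
    frac <- mean(m)
    if (frac == 0 || frac == 1) {
      stop(sprintf("degenerate mask in %s: %s", which,
                   if (frac == 0) "empty" else "full"), call. = FALSE)
    }
    m
  }
  mask_a <- seg(pair$channel_a, threshold_a, "channel_a")
  mask_b <- seg(pair$channel_b, threshold_b, "channel_b")
  cc_mask <- stats::cor(as.numeric(mask_a), as.numeric(mask_b))
  union <- mask_a | mask_b
  ia <- pair$channel_a[union]; ib <- pair$channel_b[union]
  cc_int <- if (stats::sd(ia) > 0 && stats::sd(ib) > 0) {
    stats::cor(ia, ib)
  } else {
    NA_real_  # constant intensity on the union: undefined
  }
  if (method == "intensity" && is.na(cc_int)) {
    stop("intensity correlation undefined: constant intensity on the union mask",
         call. = FALSE)
  }
  cc <- if (method == "mask") cc_mask else cc_int
  other <- if (method == "mask") cc_int else cc_mask
  attr(cc, "method") <- method
  attr(cc, "threshold_a") <- attr(mask_a, "threshold")
  attr(cc, "threshold_b") <- attr(mask_b, "threshold")
  if (is.finite(other) && abs(cc - other) > 0.1) {
    attr(cc, "cc_other") <- other
  }
  cc
}

#' Mean correlation coefficient over an experiment's images
#'
#' Averages [correlation_coefficient()] over the image pairs of one
#' experiment (classically 5 fields of view); a failure on any pair is
#' propagated with its index.
#'
#' @param pairs List of [image_pair()] objects (>= 1).
#' @param ... Passed to [correlation_coefficient()].
#' @return List with `mean_cc` and the per-image `cc` vector.
#' @export
batch_cc <- function(pairs, ...) {
  if (!is.list(pairs) || length(pairs) < 1) {
    stop("'pairs' must be a non-empty list of image pairs", call. = FALSE)
  }
  cc <- vapply(seq_along(pairs), function(i) {
    tryCatch(as.numeric(correlation_coefficient(pairs[[i]], ...)),
             error = function(e) {
               stop(sprintf("image %d: %s", i, conditionMessage(e)),
                    call. = FALSE)
             })
  }, 1)
  list(mean_cc = mean(cc), cc = cc, n_images = length(cc))
}
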