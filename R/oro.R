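# Oil Red O fat densitometry: pseudo flat-field correction, RGB channel
# separation, green-channel stain thresholding, integrated density within a
# 40-pixel-diameter measurement circle.

#' Pseudo flat-field correction of an RGB micrograph
#'
#' Removes slowly varying illumination (vignetting) per channel by dividing
#' the image by a heavily blurred copy of itself:
#' `corrected = I * K / B`, where `B` is the Gaussian blur of `I` with
#' `sigma_px` and `K` is a rescale constant. With `rescale = "max"` (default)
#' `K = max(B)`, anchoring the corrected image to the brightest illumination
#' level — so corrections of the same scene under different vignettes land on
#' a common intensity scale and their densitometry agrees. `rescale = "mean"`
#' uses `K = mean(B)`, which preserves each image's own global brightness but
#' makes images with different vignette strengths incomparable. Output is
#' clipped to `[0, value_range]`.
#'
#' @param rgb `(y, x, 3)` array (a 2-D matrix is treated as one channel of a
#'   3-channel image is an error: RGB input is required).
#' @param sigma_px Blur sigma in px, positive and much smaller than the
#'   image (default 50).
#' @param rescale `"max"` or `"mean"` (see above).
#' @param value_range Channel full scale (default 255).
#' @return Corrected `(y, x, 3)` array.
#' @export
pseudo_flat_field <- function(rgb, sigma_px = 50,
                              rescale = c("max", "mean"), value_range = 255) {
  rescale <- match.arg(rescale)
  if (!(is.numeric(sigma_px) && length(sigma_px) == 1L && sigma_px > 0)) {
    abort("`sigma_px` must be a single positive number.")
  }
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    abort("`rgb` must be a (y, x, 3) three-channel array.")
  }
  if (sigma_px >= min(dim(rgb)[1:2])) {
    abort("`sigma_px` must be much smaller than the image.")
  }
  out <- rgb
  eps <- 1e-6 * value_range
  # cap the kernel so a wide blur still fits small images (truncated Gaussian)
  radius <- min(2L * ceiling(3 * sigma_px) + 1L,
                2L * ((min(dim(rgb)[1:2]) - 1L) %/% 2L) + 1L)
  for (k in 1:3) {
    b <- EBImage::gblur(rgb[, , k], sigma = sigma_px, radius = radius,
                        boundary = "replicate")
    b <- pmax(b, eps)
    const <- if (rescale == "max") max(b) else mean(b)
    out[, , k] <- pmin(pmax(rgb[, , k] * const / b, 0), value_range)
  }
  out
}

#' Separate an RGB image into channel planes
#'
#' @param rgb `(y, x, 3)` array.
#' @return Named list of three independent `(y, x)` matrices `R`, `G`, `B`
#'   (plain copies: mutating one never affects the source).
#' @export
split_channels <- function(rgb) {
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    abort("`rgb` must be a (y, x, 3) three-channel array.")
  }
  list(R = rgb[, , 1], G = rgb[, , 2], B = rgb[, , 3])
}

#' Threshold Oil Red O stain in the green channel
#'
#' Oil Red O absorbs green light, so stained pixels are green-dark. Stain
#' intensity is defined by inversion, `S = value_range - G`, and the stain
#' mask is `S >= threshold`. The same numeric threshold must be applied to
#' every image of one experiment.
#'
#' @param green 2-D green-channel matrix.
#' @param threshold Stain-intensity threshold within `[0, value_range]`.
#' @param polarity Only `"stain_is_dark_green"` is defined.
#' @param value_range Channel full scale (default 255).
#' @return List with `mask` (logical matrix) and `stain` (the inverted
#'   stain-intensity image).
#' @export
stain_mask <- function(green, threshold, polarity = "stain_is_dark_green",
                       value_range = 255) {
  polarity <- match.arg(polarity)
  if (!is.matrix(green)) abort("`green` must be a 2-D matrix.")
  if (!(threshold >= 0 && threshold <= value_range)) {
    abort("`threshold` outside the channel range.")
  }
  stain <- value_range - green
  list(mask = stain >= threshold, stain = stain)
}

#' Integrated stain density within a measurement circle
#'
#' Sums stain intensity over pixels whose 0-based integer centers lie within
#' `diameter_px / 2` of `center_xy` AND are in the stain mask (integrated
#' density limited to thresholded signal, i.e. area times mean). Pixels
#' outside the image bounds contribute nothing; the circle must intersect
#' the image.
#'
#' @param stain 2-D stain-intensity image (see [stain_mask()]).
#' @param mask Logical stain mask, same shape.
#' @param center_xy `(x, y)` circle center, 0-based pixel coordinates.
#' @param diameter_px Circle diameter (default 40).
#' @param threshold_used Threshold recorded in the result.
#' @param subject_id,group Labels.
#' @return One-row tibble: `subject_id`, `group`, `circle_x`, `circle_y`,
#'   `circle_diameter_px`, `threshold_used`, `integrated_density`,
#'   `n_stain_pixels`.
#' @export
integrated_density <- function(stain, mask, center_xy, diameter_px = 40,
                               threshold_used = NA_real_,
                               subject_id = "subject", group = "") {
  if (!is.matrix(stain) || !is.matrix(mask) || !all(dim(stain) == dim(mask))) {
    abort("`stain` and `mask` must be matrices of one shape.")
  }
  circ <- circle_mask(dim(stain), center_xy, diameter_px)
  sel <- circ & mask
  tibble(
    subject_id = subject_id, group = group,
    circle_x = as.numeric(center_xy[1]), circle_y = as.numeric(center_xy[2]),
    circle_diameter_px = as.numeric(diameter_px),
    threshold_used = threshold_used,
    integrated_density = sum(stain[sel]),
    n_stain_pixels = sum(sel)
  )
}

#' Quantify Oil Red O staining in one micrograph
#'
#' The full per-image chain: [pseudo_flat_field()], [split_channels()],
#' [stain_mask()] on the green channel, [integrated_density()] inside the
#' measurement circle.
#'
#' @param rgb `(y, x, 3)` image, 0-255 scale.
#' @param center_xy Measurement-circle center `(x, y)`, 0-based (placed over
#'   the anterior intestinal cells by the operator).
#' @param threshold Stain-intensity threshold shared across the experiment.
#' @param sigma_px Flat-field blur sigma (default 50).
#' @param diameter_px Circle diameter (default 40).
#' @param flat_field Apply the flat-field step (default `TRUE`).
#' @param subject_id,group Labels.
#' @return One-row tibble as for [integrated_density()].
#' @export
quantify_oro <- function(rgb, center_xy, threshold, sigma_px = 50,
                         diameter_px = 40, flat_field = TRUE,
                         subject_id = "subject", group = "") {
  img <- if (flat_field) pseudo_flat_field(rgb, sigma_px = sigma_px) else rgb
  ch <- split_channels(img)
  sm <- stain_mask(ch$G, threshold)
  integrated_density(sm$stain, sm$mask, center_xy, diameter_px,
                     threshold_used = threshold,
                     subject_id = subject_id, group = group)
}
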