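# HyPer redox quantification.
#
# Lifetime gating isolates a pure-autofluorescence channel (long-lifetime,
# blue-shifted emission, no sensor signal). The autofluorescence contribution
# to each sensor channel is proportional to that channel, with a bleed ratio
# R fitted over pooled control pixels, and is removed pixel-by-pixel:
#   F_sensor = F_raw - R * F_AF
# The redox readout is then the 488ex/405ex ratio of the corrected channels.

# normalise mask input: NULL, a (y, x) logical matrix, or a roi_set row
as_roi_mask <- function(roi, shape_yx = NULL) {
  if (is.null(roi)) return(NULL)
  if (inherits(roi, "roi_set") || is.data.frame(roi)) {
    if (nrow(roi) != 1L) abort("supply exactly one ROI row.")
    roi <- roi$mask[[1]]
  }
  if (!is.matrix(roi) || !is.logical(roi)) {
    abort("ROI must be a logical (y, x) matrix or a one-row roi_set.")
  }
  if (!is.null(shape_yx) && !all(dim(roi) == shape_yx)) {
    abort("ROI mask shape does not match the image.")
  }
  roi
}

#' Fit the autofluorescence bleed ratio from control animals
#'
#' Pools every pixel of the paired (sensor-channel, AF-channel) control
#' stacks and fits the proportionality `F_target = R * F_AF` by least squares
#' through the origin, the closed form
#' `R = sum(F_target * F_AF) / sum(F_AF^2)`. The fit is through the origin
#' because the subtraction formula has no offset term; a free-intercept fit
#' is available as a diagnostic only. Because imaging parameters drift
#' between sessions, fit one model per experimental group and apply it only
#' within that group.
#'
#' @param targets Sensor-channel control stacks: a [channel_stack()]/array or
#'   a list of them (one per control animal).
#' @param afs Matching AF-channel stacks, same shapes.
#' @param channel Name of the sensor channel being corrected (default
#'   `"405"`).
#' @param mask Optional pixel mask restricting the fit: a logical `(y, x)`
#'   matrix (applied to every slice of every subject), a list of such masks
#'   (one per subject), or `NULL` to pool whole fields.
#' @param group Experimental-group label recorded on the model.
#' @param intercept If `TRUE`, also record an ordinary least-squares fit with
#'   a free intercept under `$diagnostics` (never used for correction).
#' @return An object of class `af_unmixing` with elements `r` (named bleed
#'   ratio), `channel`, `group`, `n_pixels_fit`, `rms_residual`, and
#'   `diagnostics`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' af <- matrix(1:4, 2)
#' estimate_af_ratio(0.6 * af, af)$r
estimate_af_ratio <- function(targets, afs, channel = "405", mask = NULL,
                              group = "", intercept = FALSE) {
  if (inherits(targets, "channel_stack") || is.array(targets)) targets <- list(targets)
  if (inherits(afs, "channel_stack") || is.array(afs)) afs <- list(afs)
  if (length(targets) != length(afs) || !length(targets)) {
    abort("`targets` and `afs` must be matched, nonempty lists of stacks.")
  }
  if (!is.null(mask) && !is.list(mask)) mask <- rep(list(mask), length(targets))

  tvals <- avals <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tv <- as_voxels(targets[[i]], "targets")
    av <- as_voxels(afs[[i]], "afs")
    if (!all(dim(tv) == dim(av))) abort("paired stacks must share a shape.")
    if (!is.null(mask)) {
      m <- as_roi_mask(mask[[i]], dim(tv)[2:3])
      if (!any(m)) abort("empty fit mask.")
      keep <- aperm(array(m, dim = c(dim(tv)[2:3], dim(tv)[1])), c(3, 1, 2))
      tv <- tv[keep]; av <- av[keep]
    }
    tvals[[i]] <- as.numeric(tv); avals[[i]] <- as.numeric(av)
  }
  ft <- unlist(tvals); fa <- unlist(avals)
  ssa <- sum(fa^2)
  if (ssa == 0) abort("AF channel is identically zero; bleed ratio undefined.")
  r <- sum(ft * fa) / ssa
  resid <- ft - r * fa
  diagnostics <- NULL
  if (intercept) {
    fit <- stats::lm.fit(cbind(1, fa), ft)
    diagnostics <- list(intercept = unname(fit$coefficients[1]),
                        slope = unname(fit$coefficients[2]))
  }
  structure(
    list(
      r = stats::setNames(r, channel), channel = channel, group = group,
      n_pixels_fit = length(fa),
      rms_residual = sqrt(mean(resid^2)),
      diagnostics = diagnostics
    ),
    class = "af_unmixing"
  )
}

#' @export
print.af_unmixing <- function(x, ...) {
  cat(sprintf(
    "<af_unmixing> channel %s%s: R = %.6g (n = %d pixels, rms %.3g counts)\n",
    x$channel, if (nzchar(x$group)) paste0(", group ", x$group) else "",
    x$r, x$n_pixels_fit, x$rms_residual
  ))
  invisible(x)
}

#' @rdname estimate_af_ratio
#' @param x An `af_unmixing` model.
#' @param ... Unused.
#' @export
tidy.af_unmixing <- function(x, ...) {
  tibble(term = paste0("R_", x$channel), estimate = unname(x$r),
         channel = x$channel, group = x$group)
}

#' @rdname estimate_af_ratio
#' @export
glance.af_unmixing <- function(x, ...) {
  tibble(r = unname(x$r), channel = x$channel, group = x$group,
         n_pixels_fit = x$n_pixels_fit, rms_residual = x$rms_residual)
}

#' Remove the autofluorescence contribution from a sensor channel
#'
#' Pixel-wise `corrected = raw - r * af`. Negative results are physically
#' impossible signal and are clipped to zero by default; the unclipped values
#' are kept in the `"unclipped"` attribute for diagnostics.
#'
#' @param raw Raw sensor-channel [channel_stack()] or array.
#' @param af AF-channel stack/array, same shape.
#' @param r Bleed ratio: a nonnegative scalar or an `af_unmixing` model.
#' @param clip_negative Clip negative corrected values to 0 (default `TRUE`).
#'   With `FALSE` the bare (possibly negative) array is returned.
#' @return Corrected stack (same class as `raw` when clipping is on), with
#'   attributes `r_used` and `unclipped`.
#' @export
subtract_autofluorescence <- function(raw, af, r, clip_negative = TRUE) {
  if (inherits(r, "af_unmixing")) r <- unname(r$r)
  if (!(is.numeric(r) && length(r) == 1L && is.finite(r) && r >= 0)) {
    abort("`r` must be a single finite nonnegative bleed ratio.")
  }
  rv <- as_voxels(raw, "raw")
  av <- as_voxels(af, "af")
  if (!all(dim(rv) == dim(av))) abort("`raw` and `af` must share a shape.")
  if (r == 0) return(raw)  # bit-exact identity
  corrected <- rv - r * av
  if (!clip_negative) return(corrected)
  out <- rewrap_stack(raw, pmax(corrected, 0))
  attr(out, "r_used") <- r
  attr(out, "unclipped") <- corrected
  out
}

#' Pick the quantification focal plane
#'
#' Returns the z index (1-based) of the slice with the greatest combined
#' corrected fluorescence (405 + 488) summed over the ROI; ties go to the
#' lowest z.
#'
#' @param corrected_405,corrected_488 Corrected channel stacks/arrays.
#' @param roi Head ROI: logical `(y, x)` matrix or one-row [roi_set()].
#' @return Integer z index.
#' @export
select_focal_plane <- function(corrected_405, corrected_488, roi) {
  v405 <- as_voxels(corrected_405, "corrected_405")
  v488 <- as_voxels(corrected_488, "corrected_488")
  if (!all(dim(v405) == dim(v488))) abort("stacks must share a shape.")
  m <- as_roi_mask(roi, dim(v405)[2:3])
  if (is.null(m) || !any(m)) abort("ROI is empty.")
  total <- v405 + v488
  sums <- vapply(seq_len(dim(total)[1]),
                 function(z) sum(total[z, , ][m]), 0)
  which.max(sums)  # first maximum: ties resolve to the lowest z
}

#' Compute the pixel-wise 488/405 redox ratio map
#'
#' `ratio = F488 / F405` wherever the corrected 405 denominator is at least
#' `denom_floor`; elsewhere the pixel is marked invalid (`NA` ratio). The
#' floor prevents ratio blow-up at dark pixels.
#'
#' @param corrected_488,corrected_405 Corrected channels (2-D or 3-D, same
#'   shape).
#' @param denom_floor Positive counts threshold on the 405 denominator.
#' @return Object of class `ratio_map`: list with `ratio` (numeric array,
#'   `NA` where invalid), `valid` (logical array), `denom_floor`. Has an
#'   [autoplot()] method for 2-D maps.
#' @export
compute_ratio_map <- function(corrected_488, corrected_405, denom_floor) {
  if (!(is.numeric(denom_floor) && length(denom_floor) == 1L && denom_floor > 0)) {
    abort("`denom_floor` must be a single positive number.")
  }
  f488 <- if (inherits(corrected_488, "channel_stack")) corrected_488$voxels else corrected_488
  f405 <- if (inherits(corrected_405, "channel_stack")) corrected_405$voxels else corrected_405
  if (!all(dim(f488) == dim(f405))) abort("channels must share a shape.")
  valid <- f405 >= denom_floor
  ratio <- ifelse(valid, f488 / f405, NA_real_)
  structure(list(ratio = ratio, valid = valid, denom_floor = denom_floor),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  cat(sprintf(
    "<ratio_map> %s, %d/%d valid pixels (denom floor %.3g), median ratio %.3g\n",
    paste(dim(x$valid), collapse = " x "), sum(x$valid), length(x$valid),
    x$denom_floor, median(x$ratio[x$valid])
  ))
  invisible(x)
}

# default denominator floor: 1% of the 99th percentile of corrected 405
# within the ROI at the quantification plane
default_denom_floor <- function(plane_405, roi_mask) {
  f <- 0.01 * quantile(plane_405[roi_mask], 0.99, names = FALSE)
  if (!is.finite(f) || f <= 0) f <- .Machine$double.eps
  f
}

#' Quantify one worm's HyPer redox ratio
#'
#' Selects the focal plane via [select_focal_plane()], then summarises the
#' corrected 488/405 ratio over valid ROI pixels at that plane. Two
#' estimators are computed: ratio-of-sums
#' `sum(F488) / sum(F405)` (the default report; robust to dim pixels) and
#' mean-of-ratios `mean(F488 / F405)`; both are returned, `roi_ratio` holds
#' the one named by `mode`.
#'
#' @param corrected_405,corrected_488 Corrected channel stacks.
#' @param roi Head ROI (logical matrix or one-row [roi_set()]).
#' @param mode `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @param denom_floor Positive counts; default 1 percent of the 99th
#'   percentile of corrected 405 within the ROI at the selected plane.
#' @param subject_id,group Labels; default taken from `corrected_405`'s
#'   metadata when it is a [channel_stack()].
#' @return One-row tibble: `subject_id`, `group`, `z_selected`, `roi_ratio`,
#'   `mode`, `n_valid_pixels`, `ratio_of_sums`, `mean_of_ratios`,
#'   `denom_floor`.
#' @export
quantify_worm <- function(corrected_405, corrected_488, roi,
                          mode = c("ratio_of_sums", "mean_of_ratios"),
                          denom_floor = NULL, subject_id = NULL, group = NULL) {
  mode <- match.arg(mode)
  if (is.null(subject_id)) {
    subject_id <- if (inherits(corrected_405, "channel_stack")) {
      corrected_405$subject_id
    } else "subject"
  }
  if (is.null(group)) {
    group <- if (inherits(corrected_405, "channel_stack")) corrected_405$group else ""
  }
  v405 <- as_voxels(corrected_405, "corrected_405")
  v488 <- as_voxels(corrected_488, "corrected_488")
  m <- as_roi_mask(roi, dim(v405)[2:3])
  z <- select_focal_plane(v405, v488, m)
  p405 <- v405[z, , ]; p488 <- v488[z, , ]
  if (is.null(denom_floor)) denom_floor <- default_denom_floor(p405, m)
  valid <- m & p405 >= denom_floor
  n_valid <- sum(valid)
  if (n_valid == 0) abort("no valid pixels in the ROI at the selected plane.")
  ros <- sum(p488[valid]) / sum(p405[valid])
  mor <- mean(p488[valid] / p405[valid])
  tibble(
    subject_id = subject_id, group = group, z_selected = z,
    roi_ratio = if (mode == "ratio_of_sums") ros else mor,
    mode = mode, n_valid_pixels = n_valid,
    ratio_of_sums = ros, mean_of_ratios = mor,
    denom_floor = denom_floor
  )
}

#' Render an intensity-normalized ratiometric (INR) image
#'
#' Hue encodes the ratio (clipped to `display_range` and min-max scaled onto
#' a fixed perceptual colormap); brightness encodes total signal, normalized
#' to the in-image maximum. Invalid and zero-intensity pixels render black.
#'
#' @param ratio_map A 2-D [compute_ratio_map()] result.
#' @param intensity 2-D total-signal image (typically corrected F405 + F488).
#' @param display_range `(lo, hi)` ratio display window, `lo < hi`.
#' @param colormap Vector of colors; default 256-level viridis.
#' @return `(y, x, 3)` RGB array in `[0, 1]`.
#' @export
render_inr <- function(ratio_map, intensity,
                       display_range = c(0.5, 2.5),
                       colormap = grDevices::hcl.colors(256, "viridis")) {
  stopifnot(inherits(ratio_map, "ratio_map"))
  if (length(dim(ratio_map$ratio)) != 2L) {
    abort("render_inr expects a 2-D ratio map (one focal plane).")
  }
  lo <- display_range[1]; hi <- display_range[2]
  if (!(lo < hi)) abort("degenerate display range: need lo < hi.")
  if (!all(dim(intensity) == dim(ratio_map$ratio))) {
    abort("intensity image must match the ratio map shape.")
  }
  ny <- nrow(intensity); nx <- ncol(intensity)
  scaled <- (pmin(pmax(ratio_map$ratio, lo), hi) - lo) / (hi - lo)
  idx <- pmin(pmax(round(scaled * (length(colormap) - 1)) + 1L, 1L), length(colormap))
  cmap <- t(grDevices::col2rgb(colormap)) / 255
  imax <- max(intensity, 0)
  bright <- if (imax > 0) pmax(intensity, 0) / imax else matrix(0, ny, nx)
  out <- array(0, dim = c(ny, nx, 3))
  ok <- ratio_map$valid & bright > 0
  for (k in 1:3) {
    plane <- matrix(0, ny, nx)
    plane[ok] <- cmap[idx[ok], k] * bright[ok]
    out[, , k] <- plane
  }
  out
}

#' Background-correct a plate-reader HyPer assay
#'
#' For population-scale measurements, whole-well 405 and 488 fluorescence is
#' corrected by subtracting the mean of a sensor-free background group per
#' channel; the per-well ratio is then
#' `(F488 - bg488) / (F405 - bg405)`. Wells whose corrected denominator is
#' not positive are flagged invalid and excluded from group means.
#'
#' @param wells Tibble/data frame with columns `group`, `f405`, `f488` (one
#'   row per well; extra columns pass through).
#' @param background_group Label of the background-control group.
#' @return List with `wells` (input plus `f405_corrected`, `f488_corrected`,
#'   `ratio`, `valid`) and `group_means` (per-group mean ratio over valid
#'   wells).
#' @export
platereader_hyper <- function(wells, background_group) {
  wells <- as_tibble(wells)
  if (!all(c("group", "f405", "f488") %in% names(wells))) {
    abort("`wells` needs columns group, f405, f488.")
  }
  bg <- wells[wells$group == background_group, ]
  if (!nrow(bg)) abort(sprintf("no background wells in group '%s'.", background_group))
  bg405 <- mean(bg$f405); bg488 <- mean(bg$f488)
  out <- dplyr::mutate(
    wells,
    f405_corrected = .data$f405 - bg405,
    f488_corrected = .data$f488 - bg488,
    valid = .data$f405_corrected > 0,
    ratio = ifelse(.data$valid, .data$f488_corrected / .data$f405_corrected, NA_real_)
  )
  gm <- out |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     n_valid_wells = dplyr::n(), .groups = "drop")
  list(wells = out, group_means = gm)
}
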