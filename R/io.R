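#' Declare the channel layout of a multi-page TIFF stack
#'
#' Microscope exports store one acquisition as a flat sequence of 2-D planes;
#' the layout declares how to fold that sequence back into channels. Channel
#' identity is carried by the declared [channel_spec()] names, never by plane
#' order, so acquisitions with different orderings are supported. Because raw
#' bit depth varies between instruments, the intensity scale is declared
#' explicitly: stored samples in `[0, 1]` are multiplied by `max_value` on
#' read.
#'
#' @param channels Named list of [channel_spec()] objects, in file order.
#' @param n_z Number of optical sections per channel.
#' @param max_value Full-scale intensity corresponding to a stored sample of
#'   1.0 (default 65535, i.e. 16-bit counts).
#' @param interleave `"z_fastest"` (all z of channel 1, then channel 2, ...)
#'   or `"channel_fastest"` (all channels of z 1, then z 2, ...).
#' @return A `stack_layout` list used by [read_stack()] and [write_stack()].
#' @export
stack_layout <- function(channels, n_z, max_value = 65535,
                         interleave = c("z_fastest", "channel_fastest")) {
  interleave <- match.arg(interleave)
  if (!length(channels) || !all(vapply(channels, inherits, TRUE, "channel_spec"))) {
    abort("`channels` must be a list of channel_spec objects.")
  }
  nms <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(nms)) abort("channel names must be unique within an acquisition.")
  names(channels) <- nms
  stopifnot(n_z >= 1, max_value > 0)
  structure(
    list(channels = channels, n_z = as.integer(n_z),
         max_value = as.numeric(max_value), interleave = interleave),
    class = "stack_layout"
  )
}

#' Read a multi-page TIFF into per-channel stacks
#'
#' @param path Path to a multi-page TIFF. OME-TIFF files are read plane-wise;
#'   the declared layout is authoritative for channel folding.
#' @param layout A [stack_layout()]; its declared channel count times `n_z`
#'   must equal the number of planes in the file.
#' @param subject_id,group,experiment_id Metadata attached to every returned
#'   stack.
#' @param z_step_um Axial step in micrometres.
#' @return Named list of [channel_stack()] objects, one per declared channel.
#' @export
read_stack <- function(path, layout, subject_id = "subject", group = "",
                       experiment_id = "", z_step_um = 0.34) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (!inherits(layout, "stack_layout")) abort("`layout` must be a stack_layout.")
  planes <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # greyscale stored with channels
    p
  })
  n_ch <- length(layout$channels)
  n_z <- layout$n_z
  if (length(planes) != n_ch * n_z) {
    abort(sprintf(
      "layout declares %d channels x %d slices = %d planes but file has %d.",
      n_ch, n_z, n_ch * n_z, length(planes)
    ))
  }
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  out <- vector("list", n_ch)
  names(out) <- names(layout$channels)
  for (ci in seq_len(n_ch)) {
    vox <- array(0, dim = c(n_z, ny, nx))
    for (zi in seq_len(n_z)) {
      idx <- if (layout$interleave == "z_fastest") {
        (ci - 1L) * n_z + zi
      } else {
        (zi - 1L) * n_ch + ci
      }
      vox[zi, , ] <- planes[[idx]] * layout$max_value
    }
    if (any(vox < 0)) abort("negative voxel values after intensity scaling.")
    out[[ci]] <- channel_stack(
      vox, layout$channels[[ci]], subject_id = subject_id, group = group,
      experiment_id = experiment_id, z_step_um = z_step_um
    )
  }
  wq_log(sprintf("read %d channels x %d slices from %s", n_ch, n_z, basename(path)))
  out
}

#' Write per-channel stacks to one multi-page TIFF
#'
#' The inverse of [read_stack()]: voxel intensities are divided by
#' `layout$max_value` and stored as 16-bit samples, so integer-valued data up
#' to `max_value` round-trips losslessly.
#'
#' @param stacks Named list of [channel_stack()] objects sharing one shape.
#' @param path Output file path.
#' @param layout A [stack_layout()] matching `stacks`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stacks, path, layout) {
  if (!inherits(layout, "stack_layout")) abort("`layout` must be a stack_layout.")
  if (!setequal(names(stacks), names(layout$channels))) {
    abort("`stacks` names must match the layout's channel names.")
  }
  dims <- lapply(stacks, function(s) dim(as_voxels(s)))
  if (length(unique(dims)) != 1L) abort("all channels of one subject must share a shape.")
  if (dims[[1]][1] != layout$n_z) abort("stack depth differs from layout n_z.")
  planes <- vector("list", length(stacks) * layout$n_z)
  ci <- 0L
  for (nm in names(layout$channels)) {
    ci <- ci + 1L
    vox <- as_voxels(stacks[[nm]])
    if (max(vox) > layout$max_value) abort("voxel values exceed layout max_value.")
    for (zi in seq_len(layout$n_z)) {
      idx <- if (layout$interleave == "z_fastest") {
        (ci - 1L) * layout$n_z + zi
      } else {
        (zi - 1L) * length(stacks) + ci
      }
      planes[[idx]] <- vox[zi, , ] / layout$max_value
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

# ---- regions of interest ----------------------------------------------------

#' Build an ROI set from logical masks
#'
#' An ROI set is a tibble with one row per region: `subject_id`, `name`, a
#' list-column `mask` of logical `(y, x)` matrices, the pixel count
#' `n_pixels`, and an `empty` flag.
#'
#' @param masks List of logical matrices (or a single matrix).
#' @param subject_id,name Character vectors recycled against `masks`.
#' @return A tibble of class `roi_set`.
#' @export
roi_set <- function(masks, subject_id = "subject", name = "roi") {
  if (is.matrix(masks)) masks <- list(masks)
  masks <- lapply(masks, function(m) {
    if (!is.matrix(m)) abort("each ROI mask must be a (y, x) matrix.")
    storage.mode(m) <- "logical"
    m
  })
  n <- length(masks)
  out <- tibble(
    subject_id = rep_len(as.character(subject_id), n),
    name = rep_len(as.character(name), n),
    mask = masks,
    n_pixels = vapply(masks, sum, 0L),
    empty = vapply(masks, function(m) !any(m), TRUE)
  )
  class(out) <- c("roi_set", class(out))
  out
}

#' Load regions of interest from JSON polygons or a label-mask TIFF
#'
#' JSON files hold an array of `{"subject": s, "name": n, "xy": [[x,y],...]}`
#' polygons in 0-based pixel-center coordinates; polygons are rasterized with
#' the pixel-center rule (a pixel belongs to the region iff its integer center
#' lies inside or on the boundary). Label-mask TIFFs yield one ROI per
#' distinct nonzero label. An all-zero mask file yields a single ROI flagged
#' `empty`.
#'
#' @param path `.json` polygon file or label-mask TIFF.
#' @param image_shape Length-2 integer `(ny, nx)` the masks must match.
#' @return A [roi_set()] tibble.
#' @export
load_roi <- function(path, image_shape) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    polys <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (!length(polys)) return(roi_set(list())[0, ])
    masks <- lapply(polys, function(p) {
      xy <- if (is.matrix(p$xy)) p$xy else do.call(rbind, lapply(p$xy, as.numeric))
      rasterize_polygon(xy, image_shape)
    })
    roi_set(
      masks,
      subject_id = vapply(polys, function(p) p$subject %||% "subject", ""),
      name = vapply(polys, function(p) p$name %||% "roi", "")
    )
  } else {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    lab <- round(img * 65535)
    if (!all(dim(lab) == image_shape)) {
      abort(sprintf(
        "mask shape (%d, %d) does not match image shape (%d, %d).",
        nrow(lab), ncol(lab), image_shape[1], image_shape[2]
      ))
    }
    labels <- sort(unique(lab[lab > 0]))
    if (!length(labels)) {
      return(roi_set(list(matrix(FALSE, image_shape[1], image_shape[2])),
                     name = "empty"))
    }
    roi_set(lapply(labels, function(l) lab == l),
            name = sprintf("label_%d", labels))
  }
}

#' Rasterize a polygon with the pixel-center-inside rule
#'
#' A pixel `(x, y)` (0-based integer center) is in the mask iff its center
#' lies strictly inside the polygon (even-odd rule) or on its boundary.
#' Deterministic: the same polygon always yields the same mask.
#'
#' @param xy n x 2 matrix of `(x, y)` vertices of a simple (non
#'   self-intersecting) closed polygon; the closing edge is implicit.
#' @param image_shape `(ny, nx)`.
#' @return Logical `(ny, nx)` matrix.
#' @export
rasterize_polygon <- function(xy, image_shape) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 3L) abort("polygon needs >= 3 (x, y) vertices.")
  if (polygon_self_intersects(xy)) abort("polygon is self-intersecting.")
  ny <- image_shape[1]; nx <- image_shape[2]
  mask <- matrix(FALSE, ny, nx)
  xs <- xy[, 1]; ys <- xy[, 2]
  x_rng <- max(0L, floor(min(xs))):min(nx - 1L, ceiling(max(xs)))
  y_rng <- max(0L, floor(min(ys))):min(ny - 1L, ceiling(max(ys)))
  if (!length(x_rng) || !length(y_rng)) return(mask)
  pts <- expand.grid(x = x_rng, y = y_rng)
  inside <- point_in_polygon(pts$x, pts$y, xs, ys)
  mask[cbind(pts$y + 1L, pts$x + 1L)] <- inside
  mask
}

# even-odd crossing test, boundary points counted as inside; vectorized over points
point_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_this <- abs(cross) <= tol * max(1, sqrt(seg_len2)) &
      px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    on_edge <- on_edge | on_this
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# test all non-adjacent edge pairs for proper intersection
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(FALSE)
  seg <- cbind(xy, xy[c(2:n, 1L), ])
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      if (segments_properly_intersect(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_properly_intersect <- function(a, b) {
  d1 <- cross2(b[3:4] - b[1:2], a[1:2] - b[1:2])
  d2 <- cross2(b[3:4] - b[1:2], a[3:4] - b[1:2])
  d3 <- cross2(a[3:4] - a[1:2], b[1:2] - a[1:2])
  d4 <- cross2(a[3:4] - a[1:2], b[3:4] - a[1:2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Logical mask of pixel centers inside a circle
#'
#' A pixel belongs to the disc iff its 0-based integer center lies within
#' `diameter_px / 2` (inclusive) of `center_xy`. Pixels outside the image are
#' simply absent; it is an error for the circle to miss the image entirely.
#'
#' @param image_shape `(ny, nx)`.
#' @param center_xy `(x, y)` circle center in 0-based pixel coordinates.
#' @param diameter_px Circle diameter in pixels (default 40).
#' @return Logical `(ny, nx)` matrix.
#' @export
circle_mask <- function(image_shape, center_xy, diameter_px = 40) {
  ny <- image_shape[1]; nx <- image_shape[2]
  r <- diameter_px / 2
  cx <- center_xy[1]; cy <- center_xy[2]
  if (cx < -r || cx > nx - 1 + r || cy < -r || cy > ny - 1 + r) {
    abort("circle lies fully outside the image.")
  }
  xg <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  yg <- matrix(0:(ny - 1), ny, nx)
  m <- (xg - cx)^2 + (yg - cy)^2 <= r^2
  if (!any(m)) abort("circle contains no pixel centers inside the image.")
  m
}

#' Read and validate a YAML analysis configuration
#'
#' One YAML file drives a batch run; validation happens up front so a typo
#' fails at startup, not mid-batch. Recognised top-level keys are free-form
#' except `max_value` (positive number) and `log_level`
#' (debug/info/warn/quiet), which are checked.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a YAML mapping.")
  if (!is.null(cfg$max_value) && !(is.numeric(cfg$max_value) && cfg$max_value > 0)) {
    abort("config `max_value` must be a positive number.")
  }
  if (!is.null(cfg$log_level)) {
    if (!cfg$log_level %in% c("debug", "info", "warn", "quiet")) {
      abort("config `log_level` must be one of debug/info/warn/quiet.")
    }
    options(wormquant.log_level = cfg$log_level)
  }
  cfg
}
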