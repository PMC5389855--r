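# Synthetic scenes with known ground truth.
#
# Each generator emulates the statistical structure one analysis stage
# assumes -- not worm anatomy. Ground-truth fields are returned alongside the
# rendered raw data so recovery can be asserted exactly.

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

apply_noise <- function(expected, noise, gaussian_sd = 0) {
  if (noise == "none") return(expected)
  out <- array(rpois(length(expected), lambda = expected), dim = dim(expected))
  if (noise == "poisson+gaussian" && gaussian_sd > 0) {
    out <- out + array(rnorm(length(expected), 0, gaussian_sd), dim = dim(expected))
  }
  pmax(out, 0)
}

# smooth positive 2-D field, replicated over z: sum of broad Gaussian blobs
make_af_field <- function(shape, af_field) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  kind <- af_field$kind %||% "blobs"
  if (kind == "constant") {
    return(array(af_field$value, dim = shape))
  }
  n <- af_field$n %||% 6L
  amp <- af_field$amplitude %||% c(50, 150)
  if (length(amp) == 1L) amp <- c(amp, amp)
  wid <- af_field$width_px %||% c(8, 16)
  if (length(wid) == 1L) wid <- c(wid, wid)
  f2 <- matrix(0, ny, nx)
  if (n > 0) {
    yg <- matrix(0:(ny - 1), ny, nx)
    xg <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
    for (i in seq_len(n)) {
      cy <- runif(1, 0, ny - 1); cx <- runif(1, 0, nx - 1)
      a <- runif(1, amp[1], amp[2]); w <- runif(1, wid[1], wid[2])
      f2 <- f2 + a * exp(-((yg - cy)^2 + (xg - cx)^2) / (2 * w^2))
    }
  }
  aperm(array(f2, dim = c(ny, nx, nz)), c(3, 1, 2))
}

make_ratio_field <- function(shape, ratio_field) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  kind <- ratio_field$kind %||% "constant"
  f2 <- switch(kind,
    constant = matrix(ratio_field$value %||% 1, ny, nx),
    gradient = {
      lo <- ratio_field$low %||% 1; hi <- ratio_field$high %||% 2
      matrix(rep(seq(lo, hi, length.out = nx), each = ny), ny, nx)
    },
    two_region = {
      lo <- ratio_field$low %||% 1; hi <- ratio_field$high %||% 2
      m <- matrix(lo, ny, nx); m[, (nx %/% 2 + 1):nx] <- hi; m
    },
    abort(sprintf("unknown ratio_field kind '%s'.", kind))
  )
  if (any(f2 <= 0)) abort("true ratio field must be positive.")
  aperm(array(f2, dim = c(ny, nx, nz)), c(3, 1, 2))
}

#' Parameters for a synthetic HyPer acquisition
#'
#' Defines the forward model
#' `raw_channel = sensor_true + r_true[channel] * af_true + noise`, with the
#' autofluorescence field shared across channels (measured directly, noisily,
#' in the AF channel). The sensor occupies an elliptical "head" region; its
#' 488-excited brightness is `sensor_mean` counts and its 405-excited
#' brightness is `sensor_mean / rho` so that the true 488/405 ratio equals the
#' requested field `rho` (oxidation depletes the 405-excitable fraction).
#'
#' @param shape `(z, y, x)` dimensions, all >= 1.
#' @param r_true Named nonnegative bleed ratios per sensor channel; default
#'   `c("405" = 0.35, "488" = 0)` (the 488 channel carries negligible
#'   autofluorescence after lifetime gating).
#' @param af_field Autofluorescence field spec:
#'   `list(kind = "blobs", n, amplitude = c(lo, hi), width_px = c(lo, hi))`
#'   or `list(kind = "constant", value)`. Counts.
#' @param sensor_mean Sensor brightness in the 488 channel, counts.
#' @param ratio_field True-ratio field spec: `list(kind = "constant", value)`,
#'   `list(kind = "gradient", low, high)` (along x), or
#'   `list(kind = "two_region", low, high)`.
#' @param noise `"none"`, `"poisson"`, or `"poisson+gaussian"`.
#' @param gaussian_sd Read-noise sd (counts), used with `"poisson+gaussian"`.
#' @param n_control_subjects Number of sensor-free control animals to render
#'   alongside the scene (autofluorescence only).
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   scenes.
#' @return A `hyper_scene_params` list.
#' @export
hyper_scene_params <- function(shape = c(7, 64, 64),
                               r_true = c("405" = 0.35, "488" = 0),
                               af_field = list(kind = "blobs", n = 6,
                                               amplitude = c(50, 150),
                                               width_px = c(8, 16)),
                               sensor_mean = 300,
                               ratio_field = list(kind = "constant", value = 1.8),
                               noise = c("poisson", "none", "poisson+gaussian"),
                               gaussian_sd = 0,
                               n_control_subjects = 0,
                               seed = 1) {
  noise <- match.arg(noise)
  if (length(shape) != 3L || any(shape < 1)) abort("`shape` must be three dims >= 1.")
  if (any(r_true < 0) || is.null(names(r_true))) {
    abort("`r_true` must be a named vector of nonnegative bleed ratios.")
  }
  if (sensor_mean <= 0) abort("`sensor_mean` must be positive.")
  structure(
    list(shape = as.integer(shape), r_true = r_true, af_field = af_field,
         sensor_mean = sensor_mean, ratio_field = ratio_field, noise = noise,
         gaussian_sd = gaussian_sd,
         n_control_subjects = as.integer(n_control_subjects),
         seed = as.integer(seed)),
    class = "hyper_scene_params"
  )
}

#' Generate a synthetic HyPer scene with ground truth
#'
#' Renders one sensor-bearing animal and, if requested, sensor-free control
#' animals (autofluorescence only, emulating age-matched wild-type controls)
#' that the bleed-ratio fit uses. Ground-truth fields (`af_true`, the two
#' sensor channels, `ratio_true`) are stored untouched beside the noisy raw
#' stacks.
#'
#' @param params A [hyper_scene_params()].
#' @return A list of class `hyper_scene`:
#'   `raw` (named list of [channel_stack()] for "405", "488", "AF"),
#'   `af_true`, `sensor_405_true`, `sensor_488_true`, `ratio_true` (arrays),
#'   `roi` (the head [roi_set()]), `controls` (list of control scenes, each
#'   with `raw` and `af_true`), and `params`.
#' @export
make_hyper_scene <- function(params) {
  stopifnot(inherits(params, "hyper_scene_params"))
  ch <- hyper_channels()
  shape <- params$shape
  ny <- shape[2]; nx <- shape[3]

  # elliptical head region, the quantification ROI
  yg <- matrix(0:(ny - 1), ny, nx)
  xg <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  head2d <- ((yg - (ny - 1) / 2) / (ny / 3))^2 + ((xg - (nx - 1) / 2) / (nx / 3))^2 <= 1
  head3d <- aperm(array(head2d, dim = c(ny, nx, shape[1])), c(3, 1, 2))

  scene <- with_seed(params$seed, {
    af <- make_af_field(shape, params$af_field)
    rho <- make_ratio_field(shape, params$ratio_field)
    s488 <- params$sensor_mean * head3d
    s405 <- (params$sensor_mean / rho) * head3d
    r405 <- unname(params$r_true["405"] %||% 0)
    r488 <- unname(params$r_true["488"] %||% 0)
    raw <- list(
      "405" = apply_noise(s405 + r405 * af, params$noise, params$gaussian_sd),
      "488" = apply_noise(s488 + r488 * af, params$noise, params$gaussian_sd),
      "AF"  = apply_noise(af, params$noise, params$gaussian_sd)
    )
    list(af = af, rho = rho, s405 = s405, s488 = s488, raw = raw)
  })

  wrap <- function(vox, spec, id) {
    channel_stack(vox, spec, subject_id = id, group = "synthetic",
                  experiment_id = "sim")
  }
  controls <- lapply(seq_len(params$n_control_subjects), function(i) {
    ctl <- with_seed(params$seed + i, {
      af <- make_af_field(shape, params$af_field)
      r405 <- unname(params$r_true["405"] %||% 0)
      r488 <- unname(params$r_true["488"] %||% 0)
      raw <- list(
        "405" = apply_noise(r405 * af, params$noise, params$gaussian_sd),
        "488" = apply_noise(r488 * af, params$noise, params$gaussian_sd),
        "AF"  = apply_noise(af, params$noise, params$gaussian_sd)
      )
      list(af = af, raw = raw)
    })
    id <- sprintf("control_%02d", i)
    list(
      raw = list("405" = wrap(ctl$raw[["405"]], ch[["405"]], id),
                 "488" = wrap(ctl$raw[["488"]], ch[["488"]], id),
                 "AF" = wrap(ctl$raw[["AF"]], ch[["AF"]], id)),
      af_true = ctl$af
    )
  })

  structure(
    list(
      raw = list("405" = wrap(scene$raw[["405"]], ch[["405"]], "hyper_01"),
                 "488" = wrap(scene$raw[["488"]], ch[["488"]], "hyper_01"),
                 "AF" = wrap(scene$raw[["AF"]], ch[["AF"]], "hyper_01")),
      af_true = scene$af,
      sensor_405_true = scene$s405,
      sensor_488_true = scene$s488,
      ratio_true = scene$rho,
      roi = roi_set(head2d, subject_id = "hyper_01", name = "head"),
      controls = controls,
      params = params
    ),
    class = "hyper_scene"
  )
}

#' Generate a synthetic mitochondrial-network stack
#'
#' Tubules are drawn as dilated random walks (one per z slice, drawn from a
#' seeded walk with small angular diffusion), scaled to `amplitude` counts,
#' blurred slice-wise by a Gaussian PSF and degraded with noise. The true
#' percent area is computed on the pre-blur binary mask projected over z,
#' inside `cell_mask`.
#'
#' @param shape `(z, y, x)` dimensions.
#' @param n_tubules Number of tubules (0 allowed).
#' @param tubule_radius_px Dilation radius in px, >= 1.
#' @param psf_sigma_px Gaussian blur sigma in px; 0 disables blurring.
#' @param noise `"none"` or `"poisson"`.
#' @param amplitude Tubule intensity in counts.
#' @param cell_mask Logical `(y, x)` cell-boundary mask; default whole frame.
#' @param walk_length Steps per random walk.
#' @param seed Integer seed.
#' @return List of class `mito_scene`: `stack` ([channel_stack()]),
#'   `mask_true` (2-D logical, z-projected pre-blur tubule mask),
#'   `percent_area_true`, `cell_mask`, `amplitude`.
#' @export
make_mito_scene <- function(shape = c(7, 64, 64), n_tubules = 5,
                            tubule_radius_px = 1, psf_sigma_px = 1,
                            noise = c("poisson", "none"), amplitude = 500,
                            cell_mask = NULL, walk_length = 40, seed = 1) {
  noise <- match.arg(noise)
  if (length(shape) != 3L || any(shape < 1)) abort("degenerate `shape`.")
  if (tubule_radius_px < 1) abort("`tubule_radius_px` must be >= 1 px.")
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, ny, nx)
  stopifnot(all(dim(cell_mask) == c(ny, nx)))

  brush_size <- 2L * floor(tubule_radius_px) + 1L
  brush <- EBImage::makeBrush(brush_size, shape = "disc")

  out <- with_seed(seed, {
    mask3 <- array(FALSE, dim = shape)
    if (n_tubules > 0) {
      for (i in seq_len(n_tubules)) {
        z <- sample.int(nz, 1L)
        y <- runif(1, ny * 0.15, ny * 0.85)
        x <- runif(1, nx * 0.15, nx * 0.85)
        theta <- runif(1, 0, 2 * pi)
        pts <- matrix(0, walk_length, 2)
        for (s in seq_len(walk_length)) {
          theta <- theta + rnorm(1, 0, 0.25)
          y <- min(max(y + sin(theta), 0), ny - 1)
          x <- min(max(x + cos(theta), 0), nx - 1)
          pts[s, ] <- c(y, x)
        }
        sl <- matrix(0L, ny, nx)
        sl[cbind(round(pts[, 1]) + 1L, round(pts[, 2]) + 1L)] <- 1L
        sl <- EBImage::dilate(sl, brush) > 0
        mask3[z, , ] <- mask3[z, , ] | sl
      }
    }
    stack <- amplitude * mask3
    if (psf_sigma_px > 0) {
      for (z in seq_len(nz)) {
        stack[z, , ] <- EBImage::gblur(stack[z, , ], sigma = psf_sigma_px,
                                       boundary = "replicate")
      }
      stack <- pmax(stack, 0)
    }
    stack <- apply_noise(stack, if (noise == "poisson") "poisson" else "none")
    list(mask3 = mask3, stack = stack)
  })

  mask_true <- apply(out$mask3, c(2, 3), any)
  structure(
    list(
      stack = channel_stack(out$stack, channel_spec("mito", 488, c(500, 550), c(0, 12)),
                            subject_id = "mito_01", group = "synthetic",
                            experiment_id = "sim"),
      mask_true = mask_true,
      percent_area_true = 100 * sum(mask_true & cell_mask) / sum(cell_mask),
      cell_mask = cell_mask,
      amplitude = amplitude
    ),
    class = "mito_scene"
  )
}

#' Generate a synthetic Oil Red O micrograph
#'
#' Round stain blobs absorb green (and some blue/red) from a white 8-bit
#' background; a smooth radial multiplicative vignette `V(x, y)` spanning
#' `vignette_range` then multiplies all channels. Ground truth (the stain map
#' and the integrated density inside the measurement circle) is computed
#' pre-vignette.
#'
#' @param shape `(ny, nx)` image dimensions.
#' @param n_blobs Number of stain blobs (0 allowed).
#' @param stain_intensity Green-channel absorption per stained pixel, 8-bit
#'   counts (0-255).
#' @param vignette_range `(vmin, vmax)` within `(0, 1]`; `c(1, 1)` disables
#'   vignetting.
#' @param blob_radius_px Stain blob radius in px.
#' @param blob_centers Optional `n_blobs x 2` matrix of `(x, y)` blob
#'   centers; default random positions in the central field. Explicit
#'   placement lets a scene put stain (and the measurement circle) in
#'   strongly vignetted regions, as happens when the animal's anterior lies
#'   near the frame edge.
#' @param circle_center_xy Measurement-circle center, 0-based `(x, y)`;
#'   default the first blob's center.
#' @param circle_diameter_px Measurement-circle diameter (default 40).
#' @param seed Integer seed.
#' @return List of class `oro_scene`: `rgb` (vignetted `(y, x, 3)` array,
#'   0-255), `rgb_flat` (pre-vignette), `stain_true`, `vignette`,
#'   `circle_center_xy`, `circle_diameter_px`, `integrated_density_true`,
#'   `n_stain_pixels_true`.
#' @export
make_oro_scene <- function(shape = c(128, 128), n_blobs = 4,
                           stain_intensity = 140, vignette_range = c(0.6, 1),
                           blob_radius_px = 6, blob_centers = NULL,
                           circle_center_xy = NULL,
                           circle_diameter_px = 40, seed = 1) {
  ny <- shape[1]; nx <- shape[2]
  if (any(vignette_range <= 0) || any(vignette_range > 1) ||
      vignette_range[1] > vignette_range[2]) {
    abort("`vignette_range` must lie within (0, 1] with vmin <= vmax.")
  }
  if (stain_intensity < 0 || stain_intensity > 255) {
    abort("`stain_intensity` must lie within the 8-bit channel range 0-255.")
  }

  yg <- matrix(0:(ny - 1), ny, nx)
  xg <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)

  res <- with_seed(seed, {
    stain <- matrix(0, ny, nx)
    centers <- NULL
    if (n_blobs > 0) {
      for (i in seq_len(n_blobs)) {
        if (!is.null(blob_centers)) {
          cx <- blob_centers[i, 1]; cy <- blob_centers[i, 2]
        } else {
          cy <- runif(1, ny * 0.2, ny * 0.8)
          cx <- runif(1, nx * 0.2, nx * 0.8)
        }
        centers <- rbind(centers, c(cx, cy))
        blob <- (yg - cy)^2 + (xg - cx)^2 <= blob_radius_px^2
        stain[blob] <- stain_intensity  # uniform plateaus; overlaps cap
      }
    }
    list(stain = stain, centers = centers)
  })
  stain <- res$stain

  rgb_flat <- array(255, dim = c(ny, nx, 3))
  rgb_flat[, , 1] <- 255 - 0.15 * stain   # red stain: red barely absorbed
  rgb_flat[, , 2] <- 255 - stain          # green strongly absorbed
  rgb_flat[, , 3] <- 255 - 0.8 * stain

  # radial vignette: vmax at the optical center, vmin at the farthest corner
  cy0 <- (ny - 1) / 2; cx0 <- (nx - 1) / 2
  d2 <- (yg - cy0)^2 + (xg - cx0)^2
  vig <- vignette_range[2] - (vignette_range[2] - vignette_range[1]) * d2 / max(d2)
  rgb <- rgb_flat * array(vig, dim = c(ny, nx, 3))

  if (is.null(circle_center_xy)) {
    circle_center_xy <- if (!is.null(res$centers)) res$centers[1, ] else c(cx0, cy0)
  }
  circ <- circle_mask(c(ny, nx), circle_center_xy, circle_diameter_px)
  stained_in_circle <- circ & stain > 0
  structure(
    list(
      rgb = rgb, rgb_flat = rgb_flat, stain_true = stain, vignette = vig,
      circle_center_xy = as.numeric(circle_center_xy),
      circle_diameter_px = circle_diameter_px,
      integrated_density_true = sum(stain[stained_in_circle]),
      n_stain_pixels_true = sum(stained_in_circle)
    ),
    class = "oro_scene"
  )
}

#' Simulate interval-scored lifespan cohorts
#'
#' Death times are drawn from a Gompertz distribution per group (hazard
#' `rate * exp(shape * t)`, the standard mortality-acceleration model) and
#' rounded up to the next scoring visit, reproducing the interval censoring
#' of cohorts examined every 1-3 days.
#'
#' @param n_per_group Animals per group (single value recycled, or named
#'   vector matching `gompertz`), each >= 2.
#' @param gompertz Named list of groups, each `list(shape, rate)` with both
#'   parameters positive. Units: per day. Defaults give a median lifespan of
#'   about 13 days, typical of wild type at 25 degrees C.
#' @param scoring_interval Days between scoring visits (default 2).
#' @param experiment_id Label attached to every row.
#' @param seed Integer seed.
#' @return A [tibble][tibble::tibble] cohort table: `subject_id`,
#'   `experiment_id`, `group`, `value` (death day), `value_type`
#'   (`"death_day"`), `excluded` (all `FALSE`; set it to drop lost/bagged
#'   animals from downstream statistics).
#' @export
make_lifespan_cohorts <- function(n_per_group,
                                  gompertz = list(
                                    control = list(shape = 0.35, rate = 0.003),
                                    treated = list(shape = 0.35, rate = 0.003)
                                  ),
                                  scoring_interval = 2, experiment_id = "sim",
                                  seed = 1) {
  groups <- names(gompertz)
  if (is.null(groups)) abort("`gompertz` must be a named list of groups.")
  for (g in groups) {
    p <- gompertz[[g]]
    if (!(p$shape > 0 && p$rate > 0)) {
      abort(sprintf("Gompertz parameters for group '%s' must be positive.", g))
    }
  }
  if (is.null(names(n_per_group))) {
    n_per_group <- stats::setNames(rep_len(n_per_group, length(groups)), groups)
  }
  if (any(n_per_group < 2)) abort("each group needs n >= 2.")
  if (scoring_interval <= 0) abort("`scoring_interval` must be positive.")

  with_seed(seed, {
    purrr::map_dfr(groups, function(g) {
      n <- n_per_group[[g]]
      t <- flexsurv::rgompertz(n, shape = gompertz[[g]]$shape,
                               rate = gompertz[[g]]$rate)
      day <- ceiling(t / scoring_interval) * scoring_interval
      tibble(
        subject_id = sprintf("%s_%03d", g, seq_len(n)),
        experiment_id = experiment_id,
        group = g,
        value = day,
        value_type = "death_day",
        excluded = FALSE
      )
    })
  })
}
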