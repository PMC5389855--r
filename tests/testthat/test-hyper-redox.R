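# autofluorescence unmixing and ratio quantification

test_that("exact proportionality recovers the bleed ratio exactly", {
  set.seed(21)
  af <- array(runif(4 * 8 * 8, 0, 200), c(4, 8, 8))
  fit <- estimate_af_ratio(0.6 * af, af)
  expect_equal(unname(fit$r), 0.6, tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-9)
  expect_identical(fit$n_pixels_fit, length(af))
})

test_that("through-origin least squares matches the hand-computed closed form", {
  # pooled pixels AF = 1..4, target = (2.1, 3.9, 6.2, 7.8): R = 59.7/30
  fit <- estimate_af_ratio(array(c(2.1, 3.9, 6.2, 7.8), c(1, 2, 2)),
                           array(c(1, 2, 3, 4), c(1, 2, 2)))
  expect_equal(unname(fit$r), 1.99)
})

test_that("all-zero AF channel and empty masks are rejected", {
  z <- array(0, c(2, 4, 4))
  expect_error(estimate_af_ratio(z, z), "identically zero")
  af <- array(1, c(2, 4, 4))
  expect_error(
    estimate_af_ratio(af, af, mask = matrix(FALSE, 4, 4)), "empty"
  )
})

test_that("fit matches a brute-force grid minimization of the RSS", {
  set.seed(22)
  for (i in 1:5) {
    fa <- runif(100, 0, 150)
    ft <- 0.35 * fa + rnorm(100, 0, 5)
    fit <- estimate_af_ratio(array(pmax(ft, 0), c(1, 10, 10)),
                             array(fa, c(1, 10, 10)))
    expect_lt(abs(unname(fit$r) - grid_fit_r(pmax(ft, 0), fa)), 1e-3)
  }
})

test_that("masked fits pool only in-mask pixels", {
  af <- array(rep(c(10, 20), each = 8), c(1, 4, 4))
  tg <- 0.5 * af
  tg[1, 1, 1] <- 500  # contaminated out-of-mask pixel
  m <- matrix(TRUE, 4, 4); m[1, 1] <- FALSE
  fit <- estimate_af_ratio(tg, af, mask = m)
  expect_equal(unname(fit$r), 0.5, tolerance = 1e-12)
})

test_that("tidy and glance expose the model fit", {
  af <- array(runif(16, 1, 10), c(1, 4, 4))
  fit <- estimate_af_ratio(0.4 * af, af, group = "EV", intercept = TRUE)
  td <- tidy(fit)
  expect_identical(td$term, "R_405")
  expect_equal(td$estimate, 0.4, tolerance = 1e-12)
  gl <- glance(fit)
  expect_identical(gl$group, "EV")
  expect_equal(fit$diagnostics$slope, 0.4, tolerance = 1e-9)
})

test_that("subtraction: identity at r = 0, hand value, clipping floor", {
  raw <- array(runif(3 * 6 * 6, 0, 100), c(3, 6, 6))
  af <- array(runif(3 * 6 * 6, 0, 50), c(3, 6, 6))
  expect_identical(subtract_autofluorescence(raw, af, 0), raw)

  one <- subtract_autofluorescence(array(10, c(1, 1, 1)), array(4, c(1, 1, 1)), 2)
  expect_equal(as.vector(one), 2)

  clipped <- subtract_autofluorescence(array(5, c(1, 1, 1)), array(4, c(1, 1, 1)), 2)
  expect_equal(as.vector(clipped), 0)
  expect_equal(as.vector(attr(clipped, "unclipped")), -3)
  expect_equal(
    subtract_autofluorescence(array(5, c(1, 1, 1)), array(4, c(1, 1, 1)), 2,
                              clip_negative = FALSE)[1, 1, 1], -3)
  expect_error(subtract_autofluorescence(raw, af[1:2, , ], 1), "shape")
  expect_error(subtract_autofluorescence(raw, af, -0.1), "nonnegative")
})

test_that("focal plane: argmax of in-ROI combined fluorescence, ties to lowest z", {
  roi <- matrix(TRUE, 2, 2)
  stack_of <- function(sums) {
    v <- array(0, c(length(sums), 2, 2))
    for (z in seq_along(sums)) v[z, , ] <- sums[z] / 8  # split over both channels
    v
  }
  s <- stack_of(c(100, 250, 250))
  expect_identical(select_focal_plane(s, s, roi), 2L)
  one <- array(1, c(1, 2, 2))
  expect_identical(select_focal_plane(one, one, roi), 1L)
  expect_error(select_focal_plane(one, one, matrix(FALSE, 2, 2)), "empty")
})

test_that("ratio map: floor rule, proportional fields, scale invariance", {
  f405 <- matrix(c(0, 1, 5, 10), 2, 2)
  f488 <- 2 * f405
  rm <- compute_ratio_map(f488, f405, denom_floor = 1)
  expect_identical(rm$valid, f405 >= 1)
  expect_equal(unique(rm$ratio[rm$valid]), 2)
  expect_true(all(is.na(rm$ratio[!rm$valid])))
  # scale invariance on the valid set
  rm2 <- compute_ratio_map(7 * f488, 7 * f405, denom_floor = 7)
  expect_identical(rm2$valid, rm$valid)
  expect_equal(rm2$ratio[rm2$valid], rm$ratio[rm$valid])
  expect_error(compute_ratio_map(f488, f405, 0), "positive")
})

test_that("quantify_worm computes both estimators as derived by hand", {
  # two ROI pixels: F488 = (1, 3), F405 = (1, 2)
  v405 <- array(0, c(1, 1, 2)); v405[1, 1, ] <- c(1, 2)
  v488 <- array(0, c(1, 1, 2)); v488[1, 1, ] <- c(1, 3)
  roi <- matrix(TRUE, 1, 2)
  res <- quantify_worm(v405, v488, roi, denom_floor = 0.5)
  expect_equal(res$ratio_of_sums, 4 / 3)
  expect_equal(res$mean_of_ratios, 1.25)
  expect_identical(res$roi_ratio, res$ratio_of_sums)
  expect_identical(res$n_valid_pixels, 2L)
  alt <- quantify_worm(v405, v488, roi, mode = "mean_of_ratios",
                       denom_floor = 0.5)
  expect_identical(alt$roi_ratio, alt$mean_of_ratios)

  # constant fields give the same value in both modes
  c405 <- array(2, c(2, 3, 3)); c488 <- array(3, c(2, 3, 3))
  cres <- quantify_worm(c405, c488, matrix(TRUE, 3, 3))
  expect_equal(cres$ratio_of_sums, 1.5)
  expect_equal(cres$mean_of_ratios, 1.5)
  expect_error(quantify_worm(c405, c488, matrix(TRUE, 3, 3), denom_floor = 10),
               "no valid pixels")
})

test_that("noiseless constant-rho scene is recovered end to end", {
  sc <- tiny_hyper(rho = 1.8, noise = "none")
  fit <- estimate_af_ratio(control_stacks(sc, "405"), control_stacks(sc, "AF"))
  cor405 <- subtract_autofluorescence(sc$raw[["405"]], sc$raw[["AF"]], fit)
  res <- quantify_worm(cor405, sc$raw[["488"]], sc$roi$mask[[1]])
  expect_equal(res$roi_ratio, 1.8, tolerance = 1e-10)
  expect_equal(res$mean_of_ratios, 1.8, tolerance = 1e-10)
})

test_that("scale invariance: rescaling all raw channels leaves results unchanged", {
  sc <- tiny_hyper(rho = 1.4, noise = "poisson", seed = 13)
  run <- function(scale) {
    fit <- estimate_af_ratio(
      lapply(control_stacks(sc, "405"), function(s) scale * s$voxels),
      lapply(control_stacks(sc, "AF"), function(s) scale * s$voxels)
    )
    cor405 <- subtract_autofluorescence(scale * sc$raw[["405"]]$voxels,
                                        scale * sc$raw[["AF"]]$voxels, fit)
    quantify_worm(cor405, scale * sc$raw[["488"]]$voxels, sc$roi$mask[[1]])
    }
  r1 <- run(1); r5 <- run(5)
  expect_equal(r1$roi_ratio, r5$roi_ratio, tolerance = 1e-12)
  expect_identical(r1$z_selected, r5$z_selected)
})

test_that("INR rendering: invalid and dark pixels are black, clipping uniform", {
  rmap <- compute_ratio_map(matrix(2, 4, 4), matrix(1, 4, 4), denom_floor = 0.5)
  img <- render_inr(rmap, matrix(0, 4, 4), c(1, 3))
  expect_true(all(img == 0))  # zero intensity everywhere

  rmap_invalid <- compute_ratio_map(matrix(1, 4, 4), matrix(0, 4, 4),
                                    denom_floor = 0.5)
  img2 <- render_inr(rmap_invalid, matrix(10, 4, 4), c(1, 3))
  expect_true(all(img2 == 0))  # all pixels invalid

  # ratio below lo everywhere at full intensity: uniform low-end color
  rmap_lo <- compute_ratio_map(matrix(0.1, 4, 4), matrix(1, 4, 4),
                               denom_floor = 0.5)
  img3 <- render_inr(rmap_lo, matrix(7, 4, 4), c(1, 3))
  lowcol <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")[1]) / 255
  for (k in 1:3) expect_equal(unique(as.vector(img3[, , k])), lowcol[k])
  expect_error(render_inr(rmap_lo, matrix(1, 4, 4), c(2, 2)), "degenerate")
})

test_that("plate-reader correction: hand value, identity, invalid flag", {
  wells <- tibble::tibble(
    group = c("bg", "bg", "trt", "trt"),
    f405 = c(18, 22, 100, 15),
    f488 = c(38, 42, 160, 50)
  )
  out <- platereader_hyper(wells, "bg")
  trt <- out$wells[out$wells$group == "trt", ]
  expect_equal(trt$ratio[1], (160 - 40) / (100 - 20))  # 1.5
  expect_false(trt$valid[2])  # f405 15 below background mean 20
  expect_true(is.na(trt$ratio[2]))
  gm <- out$group_means
  expect_equal(gm$mean_ratio[gm$group == "trt"], 1.5)
  expect_identical(gm$n_valid_wells[gm$group == "trt"], 1L)

  zero_bg <- tibble::tibble(group = c("bg", "x"), f405 = c(0, 10), f488 = c(0, 25))
  out2 <- platereader_hyper(zero_bg, "bg")
  expect_equal(out2$wells$ratio[2], 2.5)
  expect_error(platereader_hyper(wells, "nope"), "background")
})
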