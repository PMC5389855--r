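# small in-code fixtures shared across test files

# a constant-ratio noiseless HyPer scene, cheap enough for many tests
tiny_hyper <- function(rho = 1.8, noise = "none", seed = 1, n_controls = 2,
                       af = list(kind = "blobs", n = 4, amplitude = c(50, 150),
                                 width_px = c(6, 12))) {
  make_hyper_scene(hyper_scene_params(
    shape = c(5, 32, 32), af_field = af,
    ratio_field = list(kind = "constant", value = rho),
    noise = noise, n_control_subjects = n_controls, seed = seed
  ))
}

control_stacks <- function(scene, channel) {
  lapply(scene$controls, function(ctl) ctl$raw[[channel]])
}

# independent oracle for the bleed ratio: dense grid search over the
# residual sum of squares (never calls the closed form under test)
grid_fit_r <- function(ft, fa, r_max = 3, step = 1e-4) {
  grid <- seq(0, r_max, by = step)
  rss <- vapply(grid, function(r) sum((ft - r * fa)^2), 0)
  grid[which.min(rss)]
}

# independent oracle for two-sided rank-sum p: enumerate labelings directly
# on the pooled values (not on precomputed ranks)
perm_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_along(a)])
  sums <- utils::combn(n, length(a), function(idx) sum(ranks[idx]))
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

write_poly_json <- function(path, polys) {
  jsonlite::write_json(polys, path, auto_unbox = TRUE, digits = NA)
  path
}
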