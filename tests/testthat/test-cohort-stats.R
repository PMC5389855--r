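# group-comparison statistics

make_table <- function(...) {
  groups <- list(...)
  purrr::imap_dfr(groups, function(v, g) {
    tibble::tibble(subject_id = paste0(g, seq_along(v)),
                   experiment_id = "e1", group = g, value = v)
  })
}

test_that("relative values normalize to within-experiment control means", {
  tb <- tibble::tibble(
    experiment_id = c("e1", "e1", "e1", "e1", "e2", "e2"),
    group = c("ctl", "ctl", "trt", "trt", "ctl", "trt"),
    value = c(8, 12, 20, 30, 5, 40)
  )
  out <- relative_values(tb, "ctl")
  expect_equal(out$value[out$experiment_id == "e1" & out$group == "trt"],
               c(2, 3))
  expect_equal(out$value[out$experiment_id == "e2" & out$group == "trt"], 8)
  # control rows kept, per-experiment control mean becomes 1
  ctl_means <- out |>
    dplyr::filter(group == "ctl") |>
    dplyr::group_by(experiment_id) |>
    dplyr::summarise(m = mean(value))
  expect_equal(ctl_means$m, c(1, 1))
  # idempotent on a normalized table
  expect_equal(relative_values(out, "ctl")$value, out$value)

  # hand case: control mean 10, treatments 20/30/40 -> +200% mean
  tb2 <- make_table(ctl = c(10, 10), trt = c(20, 30, 40))
  out2 <- relative_values(tb2, "ctl")
  expect_equal(mean(out2$value[out2$group == "trt"]), 3)

  expect_error(relative_values(make_table(trt = c(1, 2)), "ctl"), "no 'ctl'")
  expect_error(relative_values(make_table(ctl = c(0, 0), trt = c(1, 2)), "ctl"),
               "zero control mean")
})

test_that("Bonferroni adjustment follows min(1, m p) and is monotone in m", {
  tb <- make_table(a = c(1, 2, 3), b = c(5, 6, 7), c = c(1.2, 2.1, 2.9))
  res <- ttest_bonferroni(tb, list(c("a", "b"), c("c", "b"), c("a", "c")))
  expect_identical(res$m_comparisons, rep(3L, 3))
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_raw))
  res_m1 <- ttest_bonferroni(tb, list(c("a", "b")), m = 1)
  expect_equal(res_m1$p_adjusted, res_m1$p_raw)  # m = 1 is the identity
  res_m50 <- ttest_bonferroni(tb, list(c("a", "c")), m = 50)
  expect_equal(res_m50$p_adjusted, 1)  # cap at 1
  # monotone in m
  p_m <- vapply(1:6, function(m)
    ttest_bonferroni(tb, list(c("a", "c")), m = m)$p_adjusted, 0)
  expect_true(all(diff(p_m) >= 0))
  expect_error(ttest_bonferroni(make_table(a = 1, b = c(1, 2)),
                                list(c("a", "b"))), "n >= 2")
})

test_that("Welch is the default; pooled t matches stats::t.test", {
  tb <- make_table(a = c(1, 2, 3, 9), b = c(4, 5, 6))
  a <- tb$value[tb$group == "a"]; b <- tb$value[tb$group == "b"]
  welch <- ttest_bonferroni(tb, list(c("a", "b")))
  expect_equal(welch$p_raw, t.test(a, b)$p.value)
  pooled <- ttest_bonferroni(tb, list(c("a", "b")), var_equal = TRUE)
  expect_equal(pooled$p_raw, t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("ANOVA: two-group F equals the squared pooled t", {
  tb <- make_table(a = c(1, 2, 3, 4), b = c(2.5, 4, 6, 7))
  an <- anova_bonferroni(tb)
  t_pooled <- t.test(tb$value[tb$group == "a"], tb$value[tb$group == "b"],
                     var.equal = TRUE)$statistic
  expect_equal(an$omnibus$statistic, unname(t_pooled)^2, tolerance = 1e-10)
})

test_that("ANOVA: identical groups give F = 0, p = 1; separation is detected", {
  same <- make_table(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  an <- anova_bonferroni(same)
  expect_equal(an$omnibus$statistic, 0)
  expect_equal(an$omnibus$p_value, 1)

  sep <- make_table(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 11, 12))
  an2 <- anova_bonferroni(sep, posthoc_pairs = list(c("c", "a"), c("b", "a")))
  expect_lt(an2$omnibus$p_value, 0.01)
  expect_identical(nrow(an2$posthoc), 2L)
  expect_lt(an2$posthoc$p_adjusted[1], 0.05)
  expect_error(anova_bonferroni(make_table(a = c(1, 2))), "2 groups")
})

test_that("rank-sum exact p matches exhaustive enumeration oracles", {
  expect_equal(wilcoxon_ranksum(c(1, 3), c(2, 4))$p_raw, 4 / 6)
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))$p_raw, 2 / 20)
  # all partitions with n_a = n_b <= 4, with and without ties
  set.seed(51)
  for (n in 2:4) {
    for (rep in 1:5) {
      a <- sample(1:8, n, replace = TRUE)
      b <- sample(1:8, n, replace = TRUE)
      expect_equal(wilcoxon_ranksum(a, b)$p_raw, perm_ranksum_p(a, b))
    }
  }
  # symmetry
  set.seed(52)
  a <- rpois(6, 12); b <- rpois(7, 15)
  expect_equal(wilcoxon_ranksum(a, b)$p_raw, wilcoxon_ranksum(b, a)$p_raw)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "nonempty")
})

test_that("rank-sum agrees with wilcox.test on tie-free data", {
  set.seed(53)
  a <- runif(8); b <- runif(9) + 0.2  # continuous: no ties
  expect_equal(wilcoxon_ranksum(a, b)$p_raw,
               wilcox.test(a, b, exact = TRUE)$p.value)
  # at large n the Edgeworth terms are tiny: the reference normal
  # approximation is an independent cross-check
  a2 <- runif(30); b2 <- runif(25) + 0.1
  expect_equal(wilcoxon_ranksum(a2, b2)$p_raw,
               wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 5e-3)
})

test_that("approximation tracks exact enumeration for combined n in 8..20", {
  # continuous outcomes, both groups n >= 3 (the worst-case gap over every
  # such tie-free configuration is below 0.02; verified by enumeration)
  set.seed(54)
  for (rep in 1:12) {
    n_a <- sample(3:10, 1); n_b <- sample(max(3, 8 - n_a):10, 1)
    a <- rnorm(n_a); b <- rnorm(n_b, 0.8)
    p_exact <- wilcoxon_ranksum(a, b, exact = TRUE)$p_raw
    p_approx <- wilcoxon_ranksum(a, b, exact = FALSE)$p_raw
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("survival summary: hand-computed moments and step curve", {
  s <- survival_summary(c(10, 20, 30))
  expect_equal(s$stats$mean, 20)
  expect_equal(s$stats$sem, 10 / sqrt(3))
  expect_equal(s$stats$median, 20)

  s2 <- survival_summary(c(5, 5, 5, 5))
  expect_equal(s2$stats$sem, 0)
  expect_equal(s2$curve$surviving[s2$curve$day == 4], 1)
  expect_equal(s2$curve$surviving[s2$curve$day == 5], 0)

  # all deaths after the horizon: S(t) = 1 throughout
  s3 <- survival_summary(c(9, 11), scoring_horizon = 7)
  expect_true(all(s3$curve$surviving == 1))
  expect_equal(max(s3$curve$day), 7)

  # even n: median averages the middle two
  expect_equal(survival_summary(c(2, 4, 6, 20))$stats$median, 5)
})

test_that("scored proportions: percentages and experiment-level comparisons", {
  tb <- tibble::tibble(
    experiment_id = rep(c("e1", "e2", "e3"), each = 8),
    group = rep(rep(c("ctl", "trt"), each = 4), 3),
    value = c(0, 0, 0, 1, 1, 1, 1, 1,
              0, 1, 0, 0, 1, 1, 1, 0,
              0, 0, 1, 0, 1, 1, 1, 1)
  )
  out <- proportion_scored(tb, comparisons = list(c("trt", "ctl")))
  expect_equal(out$percents$percent[out$percents$experiment_id == "e1" &
                                      out$percents$group == "ctl"], 25)
  # 3 of 12 -> 25% per experiment on average for ctl
  expect_equal(mean(out$percents$percent[out$percents$group == "ctl"]), 25)
  expect_identical(out$comparisons$n_a, 3L)  # N = experiments, not worms
  all_true <- tibble::tibble(experiment_id = "e1", group = "g",
                             value = c(TRUE, TRUE))
  expect_equal(proportion_scored(all_true)$percents$percent, 100)
  expect_error(proportion_scored(all_true[0, ]), "no scored")
})

test_that("the excluded flag removes animals from every operation", {
  tb <- make_table(ctl = c(10, 10), trt = c(20, 30))
  tb$excluded <- c(FALSE, FALSE, FALSE, TRUE)
  out <- relative_values(tb, "ctl")
  expect_identical(nrow(out), 3L)
  s <- survival_summary(dplyr::mutate(tb, value = value))
  expect_identical(sum(s$stats$n), 3L)
})

test_that("result plots build without error", {
  sc <- tiny_hyper(noise = "none")
  rmap <- compute_ratio_map(sc$raw[["488"]]$voxels[3, , ],
                            sc$raw[["405"]]$voxels[3, , ], denom_floor = 1)
  expect_s3_class(autoplot(rmap), "ggplot")
  s <- survival_summary(make_lifespan_cohorts(20, seed = 5))
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(plot_cohort(make_table(a = 1:5, b = 2:6)), "ggplot")
})
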