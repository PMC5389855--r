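# Group-comparison statistics for pooled per-worm outcomes: control-relative
# normalization, Bonferroni-corrected t-tests and one-way ANOVA, Wilcoxon
# rank-sum lifespan comparisons, survival summaries, scored proportions.

# honor the `excluded` flag carried by cohort tables (lost/bagged animals)
drop_excluded <- function(table) {
  if ("excluded" %in% names(table)) table[!table$excluded, , drop = FALSE] else table
}

check_cohort <- function(table, value_col = "value") {
  table <- as_tibble(table)
  need <- c("group", value_col)
  if (!all(need %in% names(table))) {
    abort(sprintf("cohort table needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (!"experiment_id" %in% names(table)) table$experiment_id <- "exp1"
  table$group <- as.character(table$group)
  table$experiment_id <- as.character(table$experiment_id)
  if (any(!nzchar(table$group)) || any(!nzchar(table$experiment_id))) {
    abort("every row needs nonempty group and experiment labels.")
  }
  drop_excluded(table)
}

#' Normalize outcomes relative to within-experiment controls
#'
#' Divides every value by the mean of the control group's values within the
#' same experiment, so experiments acquired on different days can be pooled
#' afterward. Control rows are kept (their per-experiment mean becomes
#' exactly 1). Idempotent on already-normalized tables.
#'
#' @param table Cohort tibble with columns `group`, `value`, and
#'   `experiment_id` (rows with `excluded = TRUE` are dropped first).
#' @param control_group Label of the control group; every experiment must
#'   contain at least one control row with a nonzero mean.
#' @return The table with `value` replaced by the dimensionless relative
#'   value.
#' @export
#' @examples
#' tb <- tibble::tibble(group = c("ctl", "ctl", "trt"),
#'                      experiment_id = "e1", value = c(8, 12, 30))
#' relative_values(tb, "ctl")$value  # 0.8 1.2 3.0
relative_values <- function(table, control_group) {
  table <- check_cohort(table)
  table |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::group_modify(function(df, key) {
      ctl <- df$value[df$group == control_group]
      if (!length(ctl)) {
        abort(sprintf("experiment '%s' has no '%s' control rows.",
                      key$experiment_id, control_group))
      }
      if (mean(ctl) == 0) {
        abort(sprintf("experiment '%s' has a zero control mean.", key$experiment_id))
      }
      dplyr::mutate(df, value = .data$value / mean(ctl))
    }) |>
    dplyr::ungroup()
}

bonferroni <- function(p, m) pmin(1, m * p)

normalize_comparisons <- function(comparisons) {
  if (is.data.frame(comparisons)) {
    comparisons <- purrr::pmap(comparisons[, 1:2], function(...) c(...))
  }
  if (!is.list(comparisons)) comparisons <- list(comparisons)
  lapply(comparisons, function(p) {
    if (length(p) != 2L) abort("each comparison must be a (group, control) pair.")
    as.character(p)
  })
}

#' Pairwise two-sample t-tests with Bonferroni correction
#'
#' Two-sided two-sample t-tests (Welch by default; set `var_equal = TRUE`
#' for the classical pooled-variance test) for each requested
#' (group, control) pair, with `p_adjusted = min(1, m * p_raw)`.
#'
#' @param table Cohort tibble (`group`, `value`; `excluded` honored).
#' @param comparisons List of `c(group, control)` pairs (or a two-column data
#'   frame).
#' @param m Number of comparisons for the correction; `"auto"` (default)
#'   uses the number of listed pairs.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param value_col Name of the outcome column.
#' @return Tibble, one row per comparison: `group_a`, `group_b`, `statistic`
#'   (t), `mean_a`, `mean_b`, `n_a`, `n_b`, `p_raw`, `m_comparisons`,
#'   `p_adjusted`.
#' @export
ttest_bonferroni <- function(table, comparisons, m = "auto",
                             var_equal = FALSE, value_col = "value") {
  table <- check_cohort(table, value_col)
  comparisons <- normalize_comparisons(comparisons)
  if (identical(m, "auto")) m <- length(comparisons)
  if (!(is.numeric(m) && m >= length(comparisons))) {
    abort("`m` must be \"auto\" or a number >= the comparisons listed.")
  }
  purrr::map_dfr(comparisons, function(pair) {
    a <- table[[value_col]][table$group == pair[1]]
    b <- table[[value_col]][table$group == pair[2]]
    if (length(a) < 2 || length(b) < 2) {
      abort(sprintf("groups '%s' vs '%s': both need n >= 2.", pair[1], pair[2]))
    }
    tt <- t.test(a, b, var.equal = var_equal)
    tibble(
      group_a = pair[1], group_b = pair[2],
      statistic = unname(tt$statistic),
      mean_a = mean(a), mean_b = mean(b),
      n_a = length(a), n_b = length(b),
      p_raw = tt$p.value, m_comparisons = as.integer(m),
      p_adjusted = bonferroni(tt$p.value, m)
    )
  })
}

#' One-way ANOVA with Bonferroni post-hoc pairwise tests
#'
#' Omnibus one-way ANOVA over the listed groups, then pairwise
#' pooled-variance t-tests over `posthoc_pairs` with Bonferroni correction
#' (m = number of listed pairs).
#'
#' @param table Cohort tibble.
#' @param groups Groups entering the omnibus; default all groups present
#'   (at least 2 required).
#' @param posthoc_pairs Optional list of `c(group, control)` pairs.
#' @param value_col Name of the outcome column.
#' @return List with `omnibus` (one-row tibble: `statistic` = F,
#'   `df_between`, `df_within`, `p_value`) and `posthoc` (a
#'   [ttest_bonferroni()] tibble, or `NULL`).
#' @export
anova_bonferroni <- function(table, groups = NULL, posthoc_pairs = NULL,
                             value_col = "value") {
  table <- check_cohort(table, value_col)
  if (is.null(groups)) groups <- unique(table$group)
  if (length(groups) < 2) abort("the omnibus needs at least 2 groups.")
  df <- table[table$group %in% groups, ]
  counts <- table(df$group)
  if (any(counts < 2)) abort("every group needs n >= 2.")
  df$group <- factor(df$group, levels = groups)
  fit <- aov(stats::reformulate("group", value_col), data = df)
  an <- summary(fit)[[1]]
  ssb <- an["group", "Sum Sq"]
  f <- an["group", "F value"]; p <- an["group", "Pr(>F)"]
  if (ssb == 0 || !is.finite(f)) {  # identical group means (or zero variance)
    f <- 0; p <- 1
  }
  posthoc <- NULL
  if (!is.null(posthoc_pairs)) {
    posthoc <- ttest_bonferroni(df, posthoc_pairs, var_equal = TRUE,
                                value_col = value_col)
  }
  list(
    omnibus = tibble(
      statistic = f,
      df_between = an["group", "Df"], df_within = an["Residuals", "Df"],
      p_value = p, n = nrow(df)
    ),
    posthoc = posthoc
  )
}

# null distribution of the rank-sum of group A by exhaustive enumeration of
# all C(N, n_a) assignments of the pooled midranks
ranksum_null <- function(ranks, n_a) {
  utils::combn(length(ranks), n_a, function(idx) sum(ranks[idx]))
}

#' Wilcoxon rank-sum test for two death-day cohorts
#'
#' Rank-sum statistic on midranks (ties share their average rank). For small
#' cohorts (combined n <= 20) the two-sided p-value is computed by exhaustive
#' enumeration of all assignments of the pooled ranks — exact even under the
#' heavy ties interval scoring produces. Larger cohorts use a normal
#' approximation with continuity correction, sharpened by an Edgeworth
#' expansion whose skewness and kurtosis terms are computed exactly from the
#' finite-population moments of the midrank sum (so the variance and shape
#' corrections account for ties automatically).
#'
#' @param days_a,days_b Death days (numeric, nonempty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   switches at combined n = 20.
#' @param label_a,label_b Group labels carried into the result.
#' @return One-row tibble: `group_a`, `group_b`, `statistic` (the rank sum W
#'   of group a), `n_a`, `n_b`, `p_raw`, `method`, `m_comparisons` (1),
#'   `p_adjusted` (= `p_raw`).
#' @export
#' @examples
#' wilcoxon_ranksum(c(1, 3), c(2, 4))$p_raw  # exact 4/6
wilcoxon_ranksum <- function(days_a, days_b, exact = NULL,
                             label_a = "a", label_b = "b") {
  days_a <- as.numeric(days_a); days_b <- as.numeric(days_b)
  if (!length(days_a) || !length(days_b)) abort("both groups must be nonempty.")
  n_a <- length(days_a); n_b <- length(days_b); n <- n_a + n_b
  pooled <- c(days_a, days_b)
  ranks <- rank(pooled)  # midranks
  w <- sum(ranks[seq_len(n_a)])
  if (is.null(exact)) exact <- n <= 20
  if (exact) {
    null_w <- ranksum_null(ranks, n_a)
    tol <- 1e-9
    p_le <- mean(null_w <= w + tol)
    p_ge <- mean(null_w >= w - tol)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact_enumeration"
  } else {
    # exact moments of W = sum of an n_a-subset of the midranks drawn
    # without replacement; with midranks as the population these reduce to
    # the classic tie-corrected mean/variance, plus third/fourth moments
    # feeding the Edgeworth shape correction
    x <- ranks - mean(ranks)
    s2 <- sum(x^2); s3 <- sum(x^3); s4 <- sum(x^4)
    pd <- function(d) prod(n_a - 0:(d - 1)) / prod(n - 0:(d - 1))
    e_w <- n_a * (n + 1) / 2
    mu2 <- (pd(1) - pd(2)) * s2
    mu3 <- (pd(1) - 3 * pd(2) + 2 * pd(3)) * s3
    mu4 <- s4 * (pd(1) - 7 * pd(2) + 12 * pd(3) - 6 * pd(4)) +
      s2^2 * (3 * pd(2) - 6 * pd(3) + 3 * pd(4))
    if (mu2 <= 0) {
      p <- 1
    } else {
      sg <- sqrt(mu2)
      g1 <- mu3 / sg^3
      g2 <- mu4 / mu2^2 - 3
      edge_cdf <- function(z) {
        pnorm(z) - dnorm(z) * (g1 / 6 * (z^2 - 1) +
                                 g2 / 24 * (z^3 - 3 * z) +
                                 g1^2 / 72 * (z^5 - 10 * z^3 + 15 * z))
      }
      p_le <- min(max(edge_cdf((w - e_w + 0.5) / sg), 0), 1)
      p_ge <- min(max(1 - edge_cdf((w - e_w - 0.5) / sg), 0), 1)
      p <- min(1, 2 * min(p_le, p_ge))
    }
    method <- "edgeworth_approximation"
  }
  tibble(
    group_a = label_a, group_b = label_b, statistic = w,
    n_a = n_a, n_b = n_b, p_raw = p, method = method,
    m_comparisons = 1L, p_adjusted = p
  )
}

#' Summarise survival of death-day cohorts
#'
#' Mean +/- s.e.m. (sample sd over sqrt(n); reported only for n >= 2),
#' median, and the survival curve `S(t)` = fraction of animals with death
#' day strictly greater than `t`, for `t = 0..scoring_horizon`.
#'
#' @param days Death days: a numeric vector (single cohort) or a cohort
#'   tibble with `group` and `value` columns (`excluded` honored).
#' @param scoring_horizon Last day of the reported curve; default the
#'   latest death day.
#' @return List of class `survival_summary` with `stats` (per group: `n`,
#'   `mean`, `sem`, `median`) and `curve` (per group and day: `surviving`).
#'   Has an [autoplot()] method.
#' @export
survival_summary <- function(days, scoring_horizon = NULL) {
  if (is.numeric(days)) {
    days <- tibble(group = "all", value = days)
  }
  days <- check_cohort(days)
  if (!nrow(days)) abort("no animals to summarise.")
  if (any(days$value <= 0)) abort("death days must be positive.")
  if (is.null(scoring_horizon)) scoring_horizon <- max(days$value)
  stats_tb <- days |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = ifelse(dplyr::n() >= 2, sd(.data$value) / sqrt(dplyr::n()), NA_real_),
      median = median(.data$value),
      .groups = "drop"
    )
  curve <- days |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(
      day = 0:scoring_horizon,
      surviving = vapply(0:scoring_horizon,
                         function(t) mean(.data$value > t), 0)
    )
  structure(list(stats = stats_tb, curve = curve), class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat("<survival_summary>\n")
  print(x$stats)
  invisible(x)
}

#' Percent of animals scored positive, compared across groups
#'
#' Computes the per-experiment, per-group percentage of positively scored
#' animals (e.g. displaying nuclear localization of a reporter), then
#' compares groups with [ttest_bonferroni()] on the per-experiment
#' percentages — the replicate unit is the independent experiment, not the
#' worm.
#'
#' @param table Cohort tibble with logical (or 0/1) `value` scores,
#'   `group`, `experiment_id`.
#' @param comparisons Optional `c(group, control)` pairs for
#'   [ttest_bonferroni()] on per-experiment percentages.
#' @return List with `percents` (per experiment and group: `n`, `percent`)
#'   and `comparisons` (tibble or `NULL`).
#' @export
proportion_scored <- function(table, comparisons = NULL) {
  table <- check_cohort(table)
  if (!nrow(table)) abort("no scored animals.")
  if (!all(table$value %in% c(0, 1, TRUE, FALSE))) {
    abort("scores must be logical or 0/1.")
  }
  percents <- table |>
    dplyr::group_by(.data$experiment_id, .data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     percent = 100 * mean(as.logical(.data$value)),
                     .groups = "drop")
  comp <- NULL
  if (!is.null(comparisons)) {
    comp <- ttest_bonferroni(
      dplyr::rename(percents, value = "percent"), comparisons
    )
  }
  list(percents = percents, comparisons = comp)
}
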