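# Effect sizes and classical tests shaping the effect-report tables.

#' Cohen's d with magnitude label
#'
#' Standardised mean difference `d = (mean1 - mean2) / s_pooled`,
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`; signed
#' with the first-listed sample minus the second. Magnitude labels follow
#' the extended scale on `|d|`: negligible (< 0.2), small (< 0.5), medium
#' (< 0.8), large (< 1.2), very large (< 2.0), huge (>= 2.0).
#'
#' @param sample1,sample2 Numeric vectors, each of length >= 2.
#' @return One-row tibble: `d`, `n1`, `n2`, `pooled_sd`, `magnitude`.
#' @export
cohens_d <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2 || n2 < 2) stopf("both samples need n >= 2")
  sp <- sqrt(((n1 - 1) * var(sample1) + (n2 - 1) * var(sample2)) / (n1 + n2 - 2))
  cohens_d_from_stats(mean(sample1), sd(sample1), n1, mean(sample2), sd(sample2), n2)
}

#' Cohen's d from summary statistics
#'
#' @param m1,s1,n1 Mean, SD and size of the first sample.
#' @param m2,s2,n2 Mean, SD and size of the second sample.
#' @return One-row tibble as in [cohens_d()].
#' @export
cohens_d_from_stats <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stopf("zero pooled SD: effect size undefined")
  d <- (m1 - m2) / sp
  tibble(d = d, n1 = n1, n2 = n2, pooled_sd = sp, magnitude = d_magnitude(d))
}

d_magnitude <- function(d) {
  a <- abs(d)
  cut(a, c(-Inf, 0.2, 0.5, 0.8, 1.2, 2.0, Inf),
    labels = c("negligible", "small", "medium", "large", "very large", "huge"),
    right = FALSE) |> as.character()
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom. When
#' both samples are constant with equal means the statistic is defined as 0
#' with p = 1.
#'
#' @param sample1,sample2 Numeric vectors, each of length >= 2.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
welch_t_test <- function(sample1, sample2) {
  if (length(sample1) < 2 || length(sample2) < 2) stopf("both samples need n >= 2")
  if (var(sample1) == 0 && var(sample2) == 0) {
    if (mean(sample1) == mean(sample2)) {
      return(tibble(statistic = 0, df = NA_real_, p_value = 1, method = "welch_t"))
    }
    stopf("both samples constant with different means: statistic undefined")
  }
  ht <- t.test(sample1, sample2, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, method = "welch_t")
}

as_group_list <- function(values, groups = NULL) {
  if (is.null(groups)) {
    if (!is.list(values)) stopf("provide a list of samples or values + groups")
    values
  } else {
    split(values, groups)
  }
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance
#' (`F = MS_between / MS_within`, equal-variance form).
#'
#' @param values Numeric vector, or a list of per-group samples.
#' @param groups Grouping vector (ignored when `values` is a list).
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p_value`, `method`.
#' @export
one_way_anova <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  if (length(gl) < 2 || any(lengths(gl) < 2)) stopf(">= 2 groups of >= 2 values required")
  means <- vapply(gl, mean, numeric(1))
  if (all(vapply(gl, var, numeric(1)) == 0) && length(unique(means)) > 1) {
    # infinite F: zero within-group variance with distinct means
    k <- length(gl); n <- sum(lengths(gl))
    return(tibble(statistic = Inf, df1 = k - 1, df2 = n - k, p_value = 0,
      method = "one_way_anova"))
  }
  y <- unlist(gl, use.names = FALSE)
  g <- factor(rep(seq_along(gl), lengths(gl)))
  ht <- oneway.test(y ~ g, var.equal = TRUE)
  tibble(statistic = unname(ht$statistic),
    df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
    p_value = ht$p.value, method = "one_way_anova")
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with the chi-squared approximation. When all
#' observations are identical, H = 0 and p = 1.
#'
#' @inheritParams one_way_anova
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  if (length(gl) < 2) stopf(">= 2 groups required")
  y <- unlist(gl, use.names = FALSE)
  if (length(unique(y)) == 1) {
    return(tibble(statistic = 0, df = length(gl) - 1, p_value = 1,
      method = "kruskal_wallis"))
  }
  ht <- kruskal.test(gl)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, method = "kruskal_wallis")
}

#' Effect-size table across paired conditions
#'
#' Convenience wrapper computing Cohen's d for each feature between two
#' row subsets of a feature table (first minus second).
#'
#' @param table A feature table (or any tibble with the feature columns).
#' @param rows1,rows2 Logical or integer row selectors.
#' @param features Feature columns to compare.
#' @return Tibble: one row per feature with the [cohens_d()] columns.
#' @export
effect_size_table <- function(table, rows1, rows2, features) {
  bind_rows(lapply(features, function(f) {
    bind_cols(tibble(feature = f),
      cohens_d(table[[f]][rows1], table[[f]][rows2]))
  }))
}
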