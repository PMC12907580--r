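as_table2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) || any(m != round(m))) {
    stop("a 2x2 table of non-negative integer counts is required",
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Continuity-corrected chi-square on one degree of freedom,
#' `n * (max(|ad - bc| - n/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))`, as used for
#' the pooled pre- versus post-acclimation classification-rate comparisons.
#' A table with a zero margin carries no information and returns statistic 0,
#' p = 1.
#'
#' @param table 2x2 matrix of counts (rows = groups, columns = outcome).
#' @return A `data.frame` with `method`, `statistic`, `df` and `p_value`.
#' @examples
#' chi_square_yates(matrix(c(150, 130, 71, 209), 2, byrow = TRUE))
#' @export
chi_square_yates <- function(table) {
  m <- as_table2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(data.frame(method = "chi-square (Yates)", statistic = 0,
                      df = 1, p_value = 1))
  }
  ct <- stats::chisq.test(m, correct = TRUE)
  data.frame(method = "chi-square (Yates)",
             statistic = unname(ct$statistic),
             df = unname(ct$parameter),
             p_value = ct$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test using the probability-mass rule: the p-value sums the
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table. Used for the
#' criterion-specific classification-rate comparisons. A zero-margin table
#' returns p = 1.
#'
#' @param table 2x2 matrix of counts.
#' @return A `data.frame` with `method`, `statistic` (conditional odds-ratio
#'   estimate) and `p_value`.
#' @examples
#' fisher_exact(matrix(c(13, 8, 2, 19), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table) {
  m <- as_table2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(data.frame(method = "Fisher exact", statistic = NA_real_,
                      p_value = 1))
  }
  ft <- stats::fisher.test(m)
  data.frame(method = "Fisher exact",
             statistic = unname(ft$estimate),
             p_value = ft$p.value)
}

#' Hedges' g effect size
#'
#' Small-sample-corrected standardised mean difference,
#' `g = J * (mean2 - mean1) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))` and
#' `J = 1 - 3 / (4 (n1+n2-2) - 1)`. With group 1 = females and group 2 =
#' males, positive values indicate higher male values, matching the reporting
#' convention of the cohort descriptive table.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Hedges' g (scalar).
#' @examples
#' hedges_g(164.1, 5.7, 21, 179.0, 7.6, 19) # ~2.19
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    stop("SDs must be >= 0 and not both 0", call. = FALSE)
  }
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  j <- 1 - 3 / (4 * df - 1)
  j * (mean2 - mean1) / s_pooled
}

#' Mean heat-intolerance percentage across criteria
#'
#' Unweighted arithmetic mean of the per-criterion intolerance rates; the
#' cohort-level summary reported per timepoint and sex.
#'
#' @param per_criterion_rates Numeric vector of percentages, non-empty.
#' @return Mean percentage (full precision; report at 1 decimal place).
#' @examples
#' mean_hi_percentage(c(15, 40, 37.5, 50, 67.5, 75, 90)) # 53.57 -> 53.6
#' @export
mean_hi_percentage <- function(per_criterion_rates) {
  if (length(per_criterion_rates) == 0L) {
    stop("at least one per-criterion rate is required", call. = FALSE)
  }
  mean(per_criterion_rates)
}

#' Integer counts from printed percentages
#'
#' Reconstructs the classification counts underlying a printed percentage
#' given the known denominator, rounding to the nearest integer.
#'
#' @param pct Percentage(s).
#' @param n Denominator.
#' @return Integer count(s).
#' @examples
#' counts_from_percent(c(15, 40, 37.5, 50, 67.5, 75, 90), 40)
#' @export
counts_from_percent <- function(pct, n) {
  as.integer(round(pct / 100 * n))
}

shapiro_p <- function(x) {
  if (stats::sd(x) == 0) return(0) # degenerate: treat as non-normal
  stats::shapiro.test(x)$p.value
}

#' Paired pre/post comparison with normality-driven dispatch
#'
#' Tests whether paired values changed between two timepoints. The
#' Shapiro-Wilk test on the paired differences (alpha = 0.05) selects a
#' paired t-test (normal) or a Wilcoxon signed-rank test (non-normal).
#' Identical vectors return the paired-t convention of statistic 0, p = 1.
#'
#' @param x_pre,x_post Paired numeric vectors (same participants, same
#'   order), length >= 3.
#' @return A `data.frame` with `method`, `statistic`, `p_value` and the mean
#'   difference `effect` (post minus pre).
#' @export
compare_paired <- function(x_pre, x_post) {
  if (length(x_pre) != length(x_post)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(x_pre) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- x_post - x_pre
  if (all(d == 0)) {
    return(data.frame(method = "paired t-test", statistic = 0, p_value = 1,
                      effect = 0))
  }
  if (shapiro_p(d) >= 0.05) {
    tt <- stats::t.test(d)
    data.frame(method = "paired t-test", statistic = unname(tt$statistic),
               p_value = tt$p.value, effect = mean(d))
  } else {
    wt <- stats::wilcox.test(d, exact = FALSE)
    data.frame(method = "Wilcoxon signed-rank",
               statistic = unname(wt$statistic),
               p_value = wt$p.value, effect = mean(d))
  }
}

#' Two-group comparison with normality- and variance-driven dispatch
#'
#' Both groups are screened with the Shapiro-Wilk test (alpha = 0.05); if
#' either is non-normal (or degenerate), a Wilcoxon rank-sum test is used.
#' Otherwise Levene's test selects a pooled-variance t-test (homogeneous) or
#' Welch's t-test (heterogeneous).
#'
#' @param x,y Numeric vectors, each length >= 3.
#' @return A `data.frame` with `method`, `statistic`, `p_value` and
#'   `effect` (Hedges' g of y relative to x, `NA` for the rank-sum branch
#'   with zero spread).
#' @export
compare_groups <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  normal <- shapiro_p(x) >= 0.05 && shapiro_p(y) >= 0.05
  g <- if (stats::sd(x) > 0 || stats::sd(y) > 0) {
    hedges_g(mean(x), stats::sd(x), length(x),
             mean(y), stats::sd(y), length(y))
  } else NA_real_
  if (!normal) {
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    return(data.frame(method = "Wilcoxon rank-sum",
                      statistic = unname(wt$statistic),
                      p_value = wt$p.value, effect = g))
  }
  grp <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lev <- car::leveneTest(c(x, y) ~ grp)
  equal_var <- lev[["Pr(>F)"]][1] >= 0.05
  tt <- stats::t.test(x, y, var.equal = equal_var)
  data.frame(method = if (equal_var) "pooled t-test" else "Welch t-test",
             statistic = unname(tt$statistic),
             p_value = tt$p.value, effect = g)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(p * m, 1)` for each p-value, with the family size `m` stated
#' explicitly (at least the number of p-values supplied); used for the
#' sex-based comparison family.
#'
#' @param p_values Numeric vector of p-values.
#' @param m Family size, `>= length(p_values)`.
#' @return Adjusted p-values.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 5)
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    stop("family size m must be >= number of p-values", call. = FALSE)
  }
  pmin(p_values * m, 1)
}
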