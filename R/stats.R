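#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value under the probability-ordering rule (the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed one), together with the
#' conditional maximum-likelihood odds ratio (0 and `Inf` are possible
#' with zero cells).
#'
#' @param x A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `(a, b, c, d)` filled by row.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(matrix(c(3, 0, 0, 3), 2, byrow = TRUE))  # p = 0.1
#' @export
fisher_exact <- function(x) {
  if (is.numeric(x) && length(x) == 4L)
    x <- matrix(x, 2, 2, byrow = TRUE)
  if (!is.matrix(x) || !all(dim(x) == c(2, 2)))
    stop("x must be a 2x2 table")
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("at least one count must be positive")
  ft <- stats::fisher.test(x)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' One-way analysis of variance
#'
#' Classic equal-variance one-way F test.  Degenerate input where every
#' value in the pooled sample is identical returns `F = 0`, `p = 1`; zero
#' within-group variance with distinct group means returns `F = Inf`,
#' `p = 0`.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List with `statistic` (F), `p_value`, `df_between`, `df_within`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))$statistic   # 13.5
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  if (ssw == 0 && ssb == 0) return(list(statistic = 0, p_value = 1,
                                        df_between = df1, df_within = df2))
  if (ssw == 0) return(list(statistic = Inf, p_value = 0,
                            df_between = df1, df_within = df2))
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}

#' Two-sample Student t-test with Bonferroni-corrected decision
#'
#' Two-tailed pooled-variance (Student) t-test; the significance call uses
#' `alpha / n_comparisons`, the Bonferroni correction for testing the
#' three network parameters (0.05/3, i.e. the 0.016 level) by default.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param alpha Nominal two-tailed level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 3).
#' @return List with `statistic`, `df`, `p_value`, `alpha_corrected`,
#'   `significant`.
#' @export
ttest_two_sample <- function(a, b, alpha = 0.05, n_comparisons = 3L) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  df <- length(a) + length(b) - 2L
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    tt <- if (mean(a) == mean(b)) list(statistic = 0, p_value = 1)
          else list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0)
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    tt <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  ac <- alpha / n_comparisons
  list(statistic = tt$statistic, df = df, p_value = tt$p_value,
       alpha_corrected = ac, significant = tt$p_value < ac)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).  The
#' p-value is exact (full permutation null) for `n <= 9` without ties,
#' and otherwise uses the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: zero rank variance")
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
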