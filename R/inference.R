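#' Test result container
#'
#' Lightweight S3 container shared by every hypothesis test in the
#' pipeline.
#'
#' @param test_kind One of `one_sample_t`, `welch_t`, `paired_t`,
#'   `correlation`, `jt_trend`, `chi_square`, `fisher_exact`.
#' @param statistic Test statistic.
#' @param df Degrees of freedom (may be fractional; `NA` where undefined).
#' @param p_value P-value in `[0, 1]`.
#' @param sidedness `"one"` or `"two"`.
#' @param bf10 Bayes factor in favour of the alternative, or `NA`.
#' @param n Sample size(s).
#' @param estimate Point estimate (mean, mean difference, or r).
#' @return Object of class `snarc_test`.
#' @export
snarc_test <- function(test_kind, statistic, df = NA_real_, p_value,
                       sidedness = "two", bf10 = NA_real_, n = NA,
                       estimate = NA_real_) {
  structure(
    list(test_kind = test_kind, statistic = statistic, df = df,
         p_value = p_value, sidedness = sidedness, bf10 = bf10, n = n,
         estimate = estimate),
    class = "snarc_test"
  )
}

#' @export
print.snarc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g", x$test_kind, x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %.4g", x$df))
  cat(sprintf(", p = %.4g (%s-sided)", x$p_value, x$sidedness))
  if (!is.na(x$bf10)) cat(sprintf(", BF10 = %.4g", x$bf10))
  cat("\n")
  invisible(x)
}

t_pvalue <- function(t, df, alternative) {
  switch(alternative,
         two.sided = 2 * stats::pt(-abs(t), df),
         less = stats::pt(t, df),
         greater = stats::pt(t, df, lower.tail = FALSE))
}

#' One-sample t-test with JZS Bayes factor
#'
#' `t = (mean(x) - mu0) / (sd(x)/sqrt(n))` with `df = n - 1`.  A
#' zero-variance sample with mean different from `mu0` yields an infinite
#' statistic and a zero p-value.
#'
#' @param x Numeric vector, `n >= 2`.
#' @param mu0 Null value (default 0).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param bf Attach a JZS Bayes factor? (default TRUE).
#' @param rscale Cauchy prior scale (default 0.707).
#' @return A [snarc_test()] of kind `one_sample_t`.
#' @export
one_sample_t <- function(x, mu0 = 0, alternative = "two.sided", bf = TRUE,
                         rscale = 0.707) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  one_sample_t_summary(mean(x), stats::sd(x), n, mu0, alternative, bf, rscale)
}

#' One-sample t-test from summary statistics
#'
#' Identical inference to [one_sample_t()] but starting from the printed
#' `(mean, SD, n)` triple, as needed to recompute published tables.
#'
#' @param mean,sd,n Sample mean, SD (n-1 denominator) and size.
#' @inheritParams one_sample_t
#' @return A [snarc_test()] of kind `one_sample_t`.
#' @export
one_sample_t_summary <- function(mean, sd, n, mu0 = 0,
                                 alternative = "two.sided", bf = TRUE,
                                 rscale = 0.707) {
  if (sd == 0) {
    t <- if (mean == mu0) 0 else sign(mean - mu0) * Inf
  } else {
    t <- (mean - mu0) / (sd / sqrt(n))
  }
  df <- n - 1
  p <- if (is.infinite(t)) {
    if (alternative == "two.sided" ||
        (alternative == "less" && t < 0) ||
        (alternative == "greater" && t > 0)) 0 else 1
  } else {
    t_pvalue(t, df, alternative)
  }
  bf10 <- if (bf && is.finite(t)) {
    jzs_bf(t, n, rscale = rscale,
           alternative = alternative)
  } else {
    NA_real_
  }
  snarc_test("one_sample_t", t, df, p,
             sidedness = if (alternative == "two.sided") "two" else "one",
             bf10 = bf10, n = n, estimate = mean)
}

#' Welch two-sample t-test with JZS Bayes factor
#'
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @inheritParams one_sample_t
#' @return A [snarc_test()] of kind `welch_t`.
#' @export
welch_t <- function(a, b, alternative = "two.sided", bf = TRUE,
                    rscale = 0.707) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  welch_t_summary(mean(a), stats::sd(a), length(a),
                  mean(b), stats::sd(b), length(b),
                  alternative, bf, rscale)
}

#' Welch test from summary statistics
#'
#' @param m1,s1,n1 Mean, SD and size of the first group.
#' @param m2,s2,n2 Mean, SD and size of the second group.
#' @inheritParams one_sample_t
#' @return A [snarc_test()] of kind `welch_t`.
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2,
                            alternative = "two.sided", bf = TRUE,
                            rscale = 0.707) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    df <- n1 + n2 - 2
  } else {
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  p <- if (is.infinite(t)) {
    if (alternative == "two.sided" ||
        (alternative == "less" && t < 0) ||
        (alternative == "greater" && t > 0)) 0 else 1
  } else {
    t_pvalue(t, df, alternative)
  }
  bf10 <- if (bf && is.finite(t)) {
    jzs_bf(t, n1, n2, rscale = rscale, alternative = alternative)
  } else {
    NA_real_
  }
  snarc_test("welch_t", t, df, p,
             sidedness = if (alternative == "two.sided") "two" else "one",
             bf10 = bf10, n = c(n1, n2), estimate = m1 - m2)
}

#' Paired t-test with JZS Bayes factor
#'
#' One-sample t-test on the element-wise differences `a - b`.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @inheritParams one_sample_t
#' @return A [snarc_test()] of kind `paired_t`.
#' @export
paired_t <- function(a, b, alternative = "two.sided", bf = TRUE,
                     rscale = 0.707) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  res <- one_sample_t(a - b, 0, alternative, bf, rscale)
  res$test_kind <- "paired_t"
  res
}

#' JZS default-prior Bayes factor for t-tests
#'
#' Evidence ratio BF10 for the alternative that the standardized effect
#' size delta is nonzero, with a Cauchy(0, `rscale`) prior on delta,
#' against the point null.  Two-sided values use the standard
#' inverse-gamma mixture representation of the marginal likelihood,
#' integrated numerically; one-sided values truncate the Cauchy prior to
#' the hypothesized direction and integrate the noncentral-t likelihood
#' over it.  For a two-sample test the effective sample size is
#' `n1*n2/(n1+n2)` and `df = n1 + n2 - 2`.
#'
#' @param t Observed t statistic (finite).
#' @param n1 Sample size (one-sample) or first group size.
#' @param n2 Optional second group size.
#' @param rscale Cauchy prior scale (default 0.707).
#' @param alternative `"two.sided"`, `"less"` (delta < 0) or `"greater"`.
#' @param rel_tol Relative integration tolerance (default 1e-8).
#' @return BF10 as a single positive number.
#' @export
jzs_bf <- function(t, n1, n2 = NULL, rscale = 0.707,
                   alternative = "two.sided", rel_tol = 1e-8) {
  if (!is.finite(t)) stop("t must be finite")
  if (n1 < 2) stop("need n >= 2")
  if (is.null(n2)) {
    n_eff <- n1
    df <- n1 - 1
  } else {
    if (n2 < 2) stop("need n >= 2 in each group")
    n_eff <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
  }
  if (alternative == "two.sided") {
    # marginal likelihood under g ~ InverseGamma(1/2, rscale^2/2)
    integrand <- function(g) {
      (1 + n_eff * g)^(-0.5) *
        (1 + t^2 / ((1 + n_eff * g) * df))^(-(df + 1) / 2) *
        sqrt(rscale^2 / (2 * pi)) * g^(-1.5) * exp(-rscale^2 / (2 * g))
    }
    num <- stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                            stop.on.error = TRUE)$value
    denom <- (1 + t^2 / df)^(-(df + 1) / 2)
    return(num / denom)
  }
  lower <- if (alternative == "less") -Inf else 0
  upper <- if (alternative == "less") 0 else Inf
  integrand <- function(delta) {
    suppressWarnings(
      stats::dt(t, df, ncp = delta * sqrt(n_eff))
    ) * 2 * stats::dcauchy(delta, 0, rscale)
  }
  num <- suppressWarnings(
    stats::integrate(integrand, lower, upper, rel.tol = rel_tol)
  )$value
  num / stats::dt(t, df)
}

# Gauss hypergeometric 2F1 by power series; |z| < 1, c > 0.
gauss_2f1 <- function(a, b, cc, z, tol = 1e-13, max_terms = 20000) {
  term <- 1
  s <- 1
  k <- 0
  while (abs(term) > tol * abs(s) && k < max_terms) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    k <- k + 1
  }
  s
}

#' Default Bayes factor for a Pearson correlation
#'
#' BF10 for a nonzero population correlation rho under a stretched-beta
#' prior of width `width` on (-1, 1) (the conventional default width is
#' 1/3), computed by numerically integrating the reduced likelihood of the
#' observed correlation over the prior.  Only the even part of the
#' likelihood contributes for this symmetric prior.
#'
#' @param r Observed Pearson correlation.
#' @param n Number of pairs (>= 3).
#' @param width Stretched-beta prior width (default 1/3).
#' @return BF10 as a single positive number.
#' @export
cor_bf <- function(r, n, width = 1 / 3) {
  if (n < 3) stop("need at least 3 pairs")
  if (abs(r) >= 1) stop("r must be in (-1, 1)")
  a <- 1 / width
  lik <- function(rho) {
    (1 - rho^2)^((n - 1) / 2) *
      vapply(rho, function(p) {
        gauss_2f1((n - 1) / 2, (n - 1) / 2, 0.5, (r * p)^2)
      }, 0)
  }
  prior <- function(rho) stats::dbeta((rho + 1) / 2, a, a) / 2
  stats::integrate(function(p) lik(p) * prior(p), -1, 1,
                   rel.tol = 1e-9)$value
}

#' Pearson correlation with default Bayes factor
#'
#' Two-sided t-based p-value (`t = r * sqrt((n-2)/(1-r^2))`, `df = n - 2`)
#' and a default stretched-beta Bayes factor via [cor_bf()].
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param bf Attach the Bayes factor? (default TRUE).
#' @param width Stretched-beta prior width (default 1/3).
#' @return A [snarc_test()] of kind `correlation` with `estimate = r`.
#' @export
pearson_cor <- function(x, y, bf = TRUE, width = 1 / 3) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  r <- stats::cor(x, y)
  df <- n - 2
  if (abs(r) == 1) {
    t <- sign(r) * Inf
    p <- 0
    bf10 <- NA_real_
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
    bf10 <- if (bf) cor_bf(r, n, width) else NA_real_
  }
  res <- snarc_test("correlation", t, df, p, sidedness = "two",
                    bf10 = bf10, n = n, estimate = r)
  res
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs (i < j) of
# #(x in group i < y in group j) + 0.5 * #(ties), via rank sums.
jt_statistic <- function(values, groups) {
  lev <- levels(groups)
  pieces <- split(values, groups)
  t_jt <- 0
  for (i in seq_len(length(lev) - 1)) {
    for (j in seq(i + 1, length(lev))) {
      xi <- pieces[[i]]
      yj <- pieces[[j]]
      r <- rank(c(xi, yj))
      nj <- length(yj)
      rj <- sum(r[seq(length(xi) + 1, length(xi) + nj)])
      t_jt <- t_jt + rj - nj * (nj + 1) / 2
    }
  }
  t_jt
}

#' Permutation Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of a numeric outcome across >= 3 groups in a
#' hypothesized order.  The statistic is the sum over ordered group pairs
#' (i < j) of the number of cross-group pairs with the earlier-group value
#' below the later-group value, ties counted as 1/2.  Significance is
#' assessed by permuting group labels; the add-one estimator
#' `p = (1 + #permuted T as or more extreme) / (n_perm + 1)` keeps p
#' strictly positive.
#'
#' @param values Numeric outcome.
#' @param groups Group labels, same length as `values`.
#' @param order Character vector giving the hypothesized group order for an
#'   increasing trend (defaults to the sorted unique labels).
#' @param n_perm Number of label permutations (default 2000).
#' @param alternative `"increasing"` (one-sided for the stated order),
#'   `"decreasing"`, or `"two.sided"`.
#' @param seed Optional integer seed for the permutations.
#' @return A [snarc_test()] of kind `jt_trend`; `statistic` is the observed
#'   T_JT, `n` the group sizes in hypothesized order.
#' @export
jonckheere_terpstra <- function(values, groups, order = NULL, n_perm = 2000,
                                alternative = "increasing", seed = NULL) {
  groups <- as.character(groups)
  if (is.null(order)) order <- sort(unique(groups))
  if (!all(groups %in% order)) stop("groups contains labels not in 'order'")
  if (length(order) < 3) stop("need at least 3 ordered groups")
  g <- factor(groups, levels = order)
  if (any(table(g) < 1)) stop("every group needs at least one value")
  if (!is.null(seed)) set.seed(seed)
  t_obs <- jt_statistic(values, g)
  t_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    t_perm[b] <- jt_statistic(values, sample(g))
  }
  eps <- 1e-9
  p_inc <- (1 + sum(t_perm >= t_obs - eps)) / (n_perm + 1)
  p_dec <- (1 + sum(t_perm <= t_obs + eps)) / (n_perm + 1)
  p <- switch(alternative,
              increasing = p_inc,
              decreasing = p_dec,
              two.sided = min(1, 2 * min(p_inc, p_dec)))
  res <- snarc_test("jt_trend", t_obs, NA_real_, p,
                    sidedness = if (alternative == "two.sided") "two" else "one",
                    n = as.integer(table(g)))
  res$n_permutations <- n_perm
  res$direction <- order
  res
}

#' Holm step-down multiple-testing correction
#'
#' Orders the raw p-values increasingly, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity by a running maximum, and caps at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_correction <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}
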