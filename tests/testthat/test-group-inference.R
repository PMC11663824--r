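test_that("t-tests agree with the stats::t.test oracle on raw data", {
  set.seed(3)
  for (i in 1:10) {
    x <- stats::rnorm(20, 1, 4)
    y <- stats::rnorm(15, 0, 2)
    res <- one_sample_t(x, bf = FALSE)
    ref <- stats::t.test(x)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$p_value, ref$p.value)

    resw <- welch_t(x, y, bf = FALSE)
    refw <- stats::t.test(x, y)
    expect_equal(resw$statistic, unname(refw$statistic))
    expect_equal(resw$df, unname(refw$parameter))
    expect_equal(resw$p_value, refw$p.value)

    y2 <- stats::rnorm(20)
    resp <- paired_t(x, y2, bf = FALSE)
    refp <- stats::t.test(x, y2, paired = TRUE)
    expect_equal(resp$statistic, unname(refp$statistic))
    expect_equal(resp$p_value, refp$p.value)
  }
})

test_that("summary-based t equals raw-data t on moment-matched samples", {
  x <- exact_moment_vector(130, -6.03, 6.68)
  expect_equal(mean(x), -6.03)
  expect_equal(stats::sd(x), 6.68)
  expect_equal(one_sample_t(x, bf = FALSE)$statistic,
               one_sample_t_summary(-6.03, 6.68, 130, bf = FALSE)$statistic)

  y <- exact_moment_vector(112, -3.43, 8.63)
  expect_equal(welch_t(x, y, bf = FALSE)$statistic,
               welch_t_summary(-6.03, 6.68, 130, -3.43, 8.63, 112,
                               bf = FALSE)$statistic)
})

test_that("hand-computed small-sample t values are reproduced", {
  # Welch on (1,2,3) vs (2,3,4): t = -1.2247, df = 4
  res <- welch_t(c(1, 2, 3), c(2, 3, 4), bf = FALSE)
  expect_equal(res$statistic, -sqrt(1.5), tolerance = 1e-10)
  expect_equal(res$df, 4)
  # paired differences (1,2,3): mean 2, sd 1, t = 2*sqrt(3)
  resp <- paired_t(c(2, 3, 4), c(1, 1, 1), bf = FALSE)
  expect_equal(resp$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(resp$df, 2)
  # zero-mean differences
  expect_equal(paired_t(c(1, 0, -1), c(0, 0, 0), bf = FALSE)$statistic, 0)
  # identical groups
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3), bf = FALSE)$statistic, 0)
  # mean at the null: t = 0, p = 1
  res0 <- one_sample_t(c(-1, 0, 1), bf = FALSE)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("degenerate zero-variance input reports an infinite statistic", {
  res <- one_sample_t(rep(2, 5), bf = FALSE)
  expect_true(is.infinite(res$statistic) && res$statistic > 0)
  expect_equal(res$p_value, 0)
  expect_error(one_sample_t(1), "at least 2")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("Welch df lies between min(n)-1 and n1+n2-2", {
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(3:30, 1)
    n2 <- sample(3:30, 1)
    res <- welch_t(stats::rnorm(n1, 0, stats::runif(1, 0.5, 5)),
                   stats::rnorm(n2, 0, stats::runif(1, 0.5, 5)), bf = FALSE)
    expect_gte(res$df, min(n1, n2) - 1 - 1e-9)
    expect_lte(res$df, n1 + n2 - 2 + 1e-9)
  }
})

test_that("JZS Bayes factors behave like the default Cauchy-prior test", {
  # strictly increasing in |t| at fixed n, symmetric two-sided, < 1 at t=0
  ts <- c(0, 0.5, 1, 2, 3, 5)
  bfs <- vapply(ts, function(t) jzs_bf(t, 50), 0)
  expect_true(all(diff(bfs) > 0))
  expect_lt(bfs[1], 1)
  expect_equal(jzs_bf(-2.2, 40), jzs_bf(2.2, 40), tolerance = 1e-8)
  # the directional BFs average to the two-sided BF (prior mixture identity)
  for (t in c(-2.5, 0.8)) {
    expect_equal((jzs_bf(t, 35, alternative = "less") +
                    jzs_bf(t, 35, alternative = "greater")) / 2,
                 jzs_bf(t, 35), tolerance = 1e-4)
  }
  expect_error(jzs_bf(Inf, 10), "finite")
})

test_that("correlation test matches cor.test and hand covariance", {
  res <- pearson_cor(c(1, 2, 3), c(1, 2, 4), bf = FALSE)
  expect_equal(res$estimate, 0.9820, tolerance = 1e-4)
  set.seed(21)
  x <- stats::rnorm(40)
  y <- 0.4 * x + stats::rnorm(40)
  res2 <- pearson_cor(x, y, bf = FALSE)
  ref <- stats::cor.test(x, y)
  expect_equal(res2$estimate, unname(ref$estimate))
  expect_equal(res2$p_value, ref$p.value)
  expect_error(pearson_cor(rep(1, 5), stats::rnorm(5)), "zero variance")
  # perfect correlation is the degenerate limit
  resp <- pearson_cor(1:5, 1:5, bf = FALSE)
  expect_equal(resp$estimate, 1)
  expect_equal(resp$p_value, 0)
})

test_that("Jonckheere-Terpstra permutation p converges to enumeration", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("a", "b", "c"), each = 2)
  res <- jonckheere_terpstra(vals, grp, order = c("a", "b", "c"),
                             n_perm = 5000, seed = 2)
  expect_equal(res$statistic, 12)  # every cross pair is concordant
  p_exact <- jt_enum_pvalue(vals, grp, c("a", "b", "c"))
  expect_equal(p_exact, 1 / 90, tolerance = 1e-12)
  expect_lt(abs(res$p_value - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 5000) + 2 / 5000)

  # reversing the hypothesized order of a strong trend gives p near 1
  rev <- jonckheere_terpstra(vals, grp, order = c("c", "b", "a"),
                             n_perm = 1000, seed = 3)
  expect_gt(rev$p_value, 0.9)

  # ties count one half: all-equal data sit at the null center
  tied <- jonckheere_terpstra(rep(1, 6), grp, order = c("a", "b", "c"),
                              n_perm = 200, seed = 4)
  expect_equal(tied$statistic, 6)  # 12 cross pairs, all ties
  expect_error(jonckheere_terpstra(1:4, rep(c("a", "b"), 2),
                                   order = c("a", "b")), "at least 3")
})

test_that("permutation p is never zero and matches the add-one estimator", {
  set.seed(5)
  vals <- c(stats::rnorm(5), stats::rnorm(5, 3), stats::rnorm(5, 6))
  grp <- rep(c("a", "b", "c"), each = 5)
  res <- jonckheere_terpstra(vals, grp, order = c("a", "b", "c"),
                             n_perm = 400, seed = 6)
  expect_gte(res$p_value, 1 / 401)
})

test_that("Holm correction matches the step-down oracle", {
  expect_equal(holm_correction(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correction(0.2), 0.2)
  expect_equal(holm_correction(rep(1, 4)), rep(1, 4))
  set.seed(30)
  for (i in 1:10) {
    p <- stats::runif(sample(1:12, 1))
    adj <- holm_correction(p)
    expect_equal(adj, stats::p.adjust(p, method = "holm"))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(holm_correction(c(0.5, 1.2)), "\\[0, 1\\]")
})
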