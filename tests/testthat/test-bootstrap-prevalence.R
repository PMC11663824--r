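test_that("classification follows the strict interval rule", {
  expect_equal(classify_slope(-9, -5, 5), "reliable")
  expect_equal(classify_slope(9, -5, 5), "reliable_reverse")
  expect_equal(classify_slope(0, -5, 5), "unreliable")
  # boundary equality is unreliable (strict inequalities)
  expect_equal(classify_slope(-5, -5, 5), "unreliable")
  expect_equal(classify_slope(5, -5, 5), "unreliable")
  expect_error(classify_slope(0, 2, 1), "q05")
})

test_that("constant RTs give a degenerate null and an unreliable label", {
  tr <- make_cell_trials(rep(500, 3), rep(500, 3))
  cls <- h0_bootstrap(tr, n_iter = 200, seed = 1)
  snarc <- cls[cls$effect == "SNARC", ]
  expect_equal(snarc$q05, 0)
  expect_equal(snarc$q95, 0)
  expect_equal(snarc$empirical_slope, 0)
  expect_equal(snarc$label, "unreliable")
  expect_equal(cls$label[cls$effect == "MARC"], "unreliable")
})

test_that("bootstrap classification is reproducible under a fixed seed", {
  cfg <- quiet_cfg(n = 1)
  st <- simulate_study(list(cfg), seed = 4)
  prep <- preprocess_study(st$trials)
  tt <- prep$trials[prep$trials$task == "PJ", ]
  a <- h0_bootstrap(tt, n_iter = 500, seed = 10)
  b <- h0_bootstrap(tt, n_iter = 500, seed = 10)
  expect_identical(a, b)
  c <- h0_bootstrap(tt, n_iter = 500, seed = 11)
  expect_false(identical(a$q05, c$q05))
  # PJ classifies both effects from the same resamples
  expect_setequal(a$effect, c("SNARC", "MARC"))
  # a digit with no retained trials is a hard error
  expect_error(h0_bootstrap(tt[tt$digit != 7, ], n_iter = 10, seed = 1),
               "digit 7")
})

test_that("stronger simulated slopes are labelled reliable more often", {
  slopes <- c(0, -5, -10, -20)
  props <- vapply(seq_along(slopes), function(k) {
    cfg <- group_config("g", 1, slope_mean = slopes[k], slope_sd = 0,
                        noise_sd_within = 100, error_rate = 0,
                        lapse_rate = 0)
    labels <- vapply(1:40, function(i) {
      pid <- sprintf("s%d_%02d", k, i)
      tr <- simulate_participant(cfg, pid, derive_seed(1000 + k, pid))
      tt <- filter_trials(tr[tr$task == "PJ", ])$trials
      cls <- h0_bootstrap(tt, n_iter = 1000, seed = derive_seed(77, pid))
      cls$label[cls$effect == "SNARC"]
    }, "")
    mean(labels == "reliable")
  }, 0)
  expect_true(all(diff(props) >= 0))
  expect_lt(props[1], 0.2)
  expect_gt(props[4], 0.8)
})

test_that("prevalence tables count groups by label with full rows", {
  cls <- data.frame(
    participant_id = sprintf("p%d", 1:6),
    group = rep(c("a", "b"), each = 3),
    label = c("reliable", "reliable", "unreliable",
              "reliable_reverse", "unreliable", "unreliable"),
    stringsAsFactors = FALSE
  )
  pt <- prevalence_table(cls, groups = c("a", "b"))
  expect_equal(unname(rowSums(pt$counts)), c(3, 3))
  expect_equal(pt$counts["a", "reliable"], 2)
  expect_equal(pt$percent["a", "reliable"], 100 * 2 / 3)
  expect_error(prevalence_table(cls, groups = c("a", "b", "ghost")),
               "ghost")
})

test_that("chi-square matches the closed form and the stats oracle", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  res <- chi_square_independence(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)  # all E = 15
  expect_equal(res$df, 1)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)

  same <- matrix(c(5, 6, 7, 5, 6, 7), 2, 3, byrow = TRUE)
  expect_equal(chi_square_independence(same)$statistic, 0)
  expect_error(chi_square_independence(matrix(c(-1, 2, 3, 4), 2)),
               "non-negative")
})

test_that("Fisher exact enumeration matches the hypergeometric oracle", {
  tab <- matrix(c(1, 9, 11, 3), 2, 2, byrow = TRUE)
  res <- fisher_exact_rxc(tab, method = "enumeration")
  expect_equal(res$p_value, 0.002759, tolerance = 1e-3)
  expect_equal(res$p_value, stats::fisher.test(tab)$p.value,
               tolerance = 1e-10)
  # identical rows with equal margins: every table is as extreme
  even <- matrix(c(2, 2, 2, 2), 2, 2)
  expect_equal(fisher_exact_rxc(even)$p_value, 1)
  # r x c case against the stats oracle
  tab3 <- matrix(c(4, 1, 3, 2, 5, 0, 1, 2, 6), 3, 3, byrow = TRUE)
  expect_equal(fisher_exact_rxc(tab3)$p_value,
               stats::fisher.test(tab3)$p.value, tolerance = 1e-8)
  expect_error(fisher_exact_rxc(matrix(c(0, 0, 1, 2), 2)), "degenerate")
})

test_that("Monte-Carlo Fisher agrees with enumeration within 3 SE", {
  tab <- matrix(c(3, 7, 8, 2), 2, 2, byrow = TRUE)
  exact <- fisher_exact_rxc(tab, method = "enumeration")$p_value
  mc <- fisher_exact_rxc(tab, method = "monte_carlo", n_mc = 20000,
                         seed = 9)
  expect_equal(mc$method, "monte_carlo")
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(mc$p_value - exact), 3 * se + 2 / 20000)
})

test_that("bootstrap_study attaches groups and derived seeds", {
  cfg <- quiet_cfg(n = 2)
  st <- simulate_study(list(cfg), seed = 14)
  prep <- preprocess_study(st$trials)
  cls <- bootstrap_study(prep$trials, n_iter = 300, master_seed = 14)
  # 2 participants x (PJ SNARC + PJ MARC + MC SNARC)
  expect_equal(nrow(cls), 6)
  expect_true(all(cls$group == "g"))
  cls2 <- bootstrap_study(prep$trials, n_iter = 300, master_seed = 14)
  expect_identical(cls, cls2)
})
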