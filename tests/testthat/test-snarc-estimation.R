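digits <- c(1, 2, 3, 4, 6, 7, 8, 9)
parity <- ifelse(digits %% 2 == 0, 0.5, -0.5)

test_that("compute_drt is right-mean minus left-mean per digit", {
  tr <- make_cell_trials(rt_left = c(500, 520), rt_right = c(480, 500))
  prof <- compute_drt(tr)
  expect_equal(unname(prof$drt), rep(-20, 8))
  expect_equal(prof$small, -20)
  expect_equal(prof$large, -20)

  # symmetric data: identical left and right multisets give all-zero dRT
  sym <- make_cell_trials(rt_left = c(450, 600, 700),
                          rt_right = c(450, 600, 700))
  expect_equal(unname(compute_drt(sym)$drt), rep(0, 8))

  # empty cell errors name the digit and side
  broken <- tr[!(tr$digit == 7 & tr$response_side == "left"), ]
  expect_error(compute_drt(broken), "digit 7, side left")
})

test_that("parity-judgment fit recovers exact linear and parity patterns", {
  est <- fit_pj_model(drt_profile(10 - 2 * digits))
  expect_equal(est$b_mag, -2)
  expect_equal(est$b_par, 0, tolerance = 1e-12)
  expect_equal(est$intercept, 10)

  # pure parity alternation: odd +5, even -5 with the -0.5/+0.5 contrast
  est2 <- fit_pj_model(drt_profile(ifelse(digits %% 2 == 0, -5, 5)))
  expect_equal(est2$b_mag, 0, tolerance = 1e-12)
  expect_equal(est2$b_par, -10)
  expect_equal(est2$z_mag, 0, tolerance = 1e-12)

  est3 <- fit_pj_model(drt_profile(rep(0, 8)))
  expect_equal(c(est3$b_mag, est3$b_par, est3$intercept,
                 est3$z_mag, est3$z_par), rep(0, 5))

  expect_error(fit_pj_model(drt_profile(c(1, NA, 1, 1, 1, 1, 1, 1))),
               "non-finite")
})

test_that("magnitude-classification models match their closed forms", {
  prof <- drt_profile(c(10, 10, 10, 10, -10, -10, -10, -10))
  fits <- fit_mc_models(prof)
  expect_equal(fits$categorical$b_mag, -20)

  step <- drt_profile(c(-1, -1, -1, -1, 1, 1, 1, 1))
  fits2 <- fit_mc_models(step)
  expect_equal(fits2$categorical$b_mag, 2)
  # continuous: Sxy/Sxx = 20/60 on the centered magnitudes
  expect_equal(fits2$continuous$b_mag, 1 / 3)

  lin <- drt_profile(3 - 1.5 * digits)
  fits3 <- fit_mc_models(lin)
  expect_equal(fits3$continuous$b_mag, -1.5)
  expect_lt(fits3$categorical$b_mag, 0)
})

test_that("categorical slope equals the category mean difference exactly", {
  set.seed(7)
  for (i in 1:20) {
    prof <- drt_profile(stats::rnorm(8, 0, 30))
    fits <- fit_mc_models(prof)
    expect_equal(fits$categorical$b_mag, prof$large - prof$small,
                 tolerance = 1e-12)
  }
})

test_that("standardized slopes are clamped correlations on the Fisher-z scale", {
  # perfectly linear decreasing profile: weight -> -1, clamped but finite
  est <- fit_pj_model(drt_profile(-3 * digits))
  expect_true(is.finite(est$z_mag))
  expect_equal(est$z_mag, atanh(-(1 - 1e-12)))

  # profile 5 - d is linear in the digit, so the correlation is exactly -1
  prof <- drt_profile(c(4, 3, 2, 1, -1, -2, -3, -4))
  expect_equal(stats::cor(prof$drt, digits), -1)
  expect_equal(fit_pj_model(prof)$z_mag, atanh(-(1 - 1e-12)))

  # moderate profile: z equals atanh of the zero-order correlation
  set.seed(12)
  y <- stats::rnorm(8)
  est2 <- fit_pj_model(drt_profile(y))
  expect_equal(est2$z_mag, atanh(stats::cor(y, digits)))
  expect_equal(est2$z_par, atanh(stats::cor(y, parity)))
})

test_that("OLS coefficients match the normal-equations oracle to 1e-10", {
  set.seed(99)
  X_pj <- cbind(1, digits, parity)
  X_cont <- cbind(1, digits)
  X_cat <- cbind(1, ifelse(digits > 5, 0.5, -0.5))
  for (i in 1:25) {
    y <- stats::rnorm(8, 0, 50)
    est <- fit_pj_model(drt_profile(y))
    oracle <- ols_oracle(X_pj, y)
    expect_equal(c(est$intercept, est$b_mag, est$b_par), oracle,
                 tolerance = 1e-10)
    fits <- fit_mc_models(drt_profile(y))
    expect_equal(c(fits$continuous$intercept, fits$continuous$b_mag),
                 ols_oracle(X_cont, y), tolerance = 1e-10)
    expect_equal(c(fits$categorical$intercept, fits$categorical$b_mag),
                 ols_oracle(X_cat, y), tolerance = 1e-10)
    # orthogonality: the parity term never moves the magnitude coefficient
    expect_equal(est$b_mag, ols_oracle(X_cont, y)[2], tolerance = 1e-10)
  }
})

test_that("group curve fit reports adjusted R-squared", {
  lin <- lapply(1:3, function(i) drt_profile(5 - 2 * digits))
  expect_equal(group_curve_fit(lin, "continuous")$adj_r_squared, 1)

  step <- lapply(1:2, function(i) drt_profile(c(-1, -1, -1, -1, 1, 1, 1, 1)))
  expect_equal(group_curve_fit(step, "categorical")$adj_r_squared, 1)
  cont <- group_curve_fit(step, "continuous")
  expect_equal(cont$r_squared, 20^2 / (60 * 8), tolerance = 1e-12)
  expect_equal(cont$adj_r_squared, 1 - (1 - 5 / 6) * 7 / 6,
               tolerance = 1e-12)

  expect_error(group_curve_fit(lin[1], "continuous"), "at least 2")
})

test_that("estimate_slopes produces the tidy per-participant table", {
  cfg <- quiet_cfg(n = 2)
  st <- simulate_study(list(cfg), seed = 17)
  prep <- preprocess_study(st$trials)
  sl <- estimate_slopes(prep$trials)
  expect_equal(sort(unique(sl$model)),
               c("mc_categorical", "mc_continuous", "pj_linear"))
  expect_equal(nrow(sl), 2 * 3)
  expect_true(all(is.na(sl$b_par[sl$task == "MC"])))
  expect_true(all(is.finite(sl$b_mag)))
})
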