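#' Per-digit right-minus-left RT differences
#'
#' For each digit, dRT is the mean RT of right-hand responses minus the
#' mean RT of left-hand responses, computed on retained (correct, filtered)
#' trials.  Also returns the small/large category means used by the
#' categorical magnitude model.
#'
#' @param trials Retained trials of one participant and one task.
#' @param digits Digit set of the design.
#' @return An object of class `drt_profile`: list with `drt` (named numeric
#'   vector over the digits), `small` and `large` (category mean dRTs).
#' @export
compute_drt <- function(trials, digits = DIGITS) {
  drt <- vapply(digits, function(d) {
    right <- trials$rt_ms[trials$digit == d & trials$response_side == "right"]
    left <- trials$rt_ms[trials$digit == d & trials$response_side == "left"]
    if (length(right) == 0) {
      stop(sprintf("no retained trials for digit %d, side right", d))
    }
    if (length(left) == 0) {
      stop(sprintf("no retained trials for digit %d, side left", d))
    }
    mean(right) - mean(left)
  }, 0)
  names(drt) <- digits
  structure(
    list(drt = drt,
         small = mean(drt[digits < 5]),
         large = mean(drt[digits > 5]),
         digits = digits),
    class = "drt_profile"
  )
}

#' Build a dRT profile from raw per-digit values
#'
#' Convenience constructor used in tests and when profiles come from
#' external sources.
#'
#' @param drt Numeric vector of 8 per-digit dRTs, ordered as `digits`.
#' @param digits Digit set.
#' @return A `drt_profile`.
#' @export
drt_profile <- function(drt, digits = DIGITS) {
  stopifnot(length(drt) == length(digits), is.numeric(drt))
  drt <- as.numeric(drt)
  names(drt) <- digits
  structure(
    list(drt = drt, small = mean(drt[digits < 5]),
         large = mean(drt[digits > 5]), digits = digits),
    class = "drt_profile"
  )
}

parity_contrast <- function(digits) ifelse(digits %% 2 == 0, 0.5, -0.5)

# Fisher-z of the standardized regression weight. In the orthogonal designs
# used here the standardized weight equals the zero-order correlation of
# dRT with the predictor; a zero-variance outcome is mapped to weight 0.
fisher_z_weight <- function(y, x, clamp = 1 - 1e-12) {
  if (stats::sd(y) == 0 || stats::sd(x) == 0) return(0)
  w <- stats::cor(y, x)
  w <- max(min(w, clamp), -clamp)
  atanh(w)
}

#' Fit the parity-judgment slope model
#'
#' OLS of the 8 per-digit dRTs on digit magnitude (linear predictor 1, 2,
#' 3, 4, 6, 7, 8, 9) and the parity contrast (-0.5 odd / +0.5 even), with
#' intercept.  The magnitude coefficient is the unstandardized SNARC slope
#' and the parity coefficient the unstandardized MARC slope; because the
#' two predictors are orthogonal in this design, the magnitude coefficient
#' is identical with or without the parity term.  Fisher-z standardized
#' weights are the atanh of the zero-order correlations (clamped to
#' +/-(1 - 1e-12)).
#'
#' @param profile A `drt_profile`.
#' @return An object of class `slope_estimate`: list with `task`, `model`,
#'   `b_mag`, `b_par`, `intercept`, `z_mag`, `z_par`.
#' @export
fit_pj_model <- function(profile) {
  stopifnot(inherits(profile, "drt_profile"))
  y <- profile$drt
  if (any(!is.finite(y))) stop("non-finite dRT value")
  mag <- profile$digits
  par_c <- parity_contrast(profile$digits)
  fit <- stats::lm(y ~ mag + par_c)
  co <- stats::coef(fit)
  structure(
    list(task = "PJ", model = "pj_linear",
         b_mag = unname(co["mag"]), b_par = unname(co["par_c"]),
         intercept = unname(co["(Intercept)"]),
         z_mag = fisher_z_weight(y, mag),
         z_par = fisher_z_weight(y, par_c)),
    class = "slope_estimate"
  )
}

#' Fit the magnitude-classification slope models
#'
#' Categorical model: dRT regressed on a -0.5 (small: 1--4) / +0.5 (large:
#' 6--9) predictor, so the slope equals dRT(large) - dRT(small) exactly.
#' Continuous model: OLS of the 8 per-digit dRTs on digit magnitude (no
#' parity predictor), comparable with the parity-judgment slope.
#'
#' @param profile A `drt_profile`.
#' @return List with elements `categorical` and `continuous`, each a
#'   `slope_estimate` (with `b_par`/`z_par` set to `NA`).
#' @export
fit_mc_models <- function(profile) {
  stopifnot(inherits(profile, "drt_profile"))
  y <- profile$drt
  if (any(!is.finite(y))) stop("non-finite dRT value")
  cat_code <- ifelse(profile$digits > 5, 0.5, -0.5)
  fit_cat <- stats::lm(y ~ cat_code)
  mag <- profile$digits
  fit_cont <- stats::lm(y ~ mag)
  list(
    categorical = structure(
      list(task = "MC", model = "mc_categorical",
           b_mag = unname(stats::coef(fit_cat)["cat_code"]), b_par = NA_real_,
           intercept = unname(stats::coef(fit_cat)["(Intercept)"]),
           z_mag = fisher_z_weight(y, cat_code), z_par = NA_real_),
      class = "slope_estimate"
    ),
    continuous = structure(
      list(task = "MC", model = "mc_continuous",
           b_mag = unname(stats::coef(fit_cont)["mag"]), b_par = NA_real_,
           intercept = unname(stats::coef(fit_cont)["(Intercept)"]),
           z_mag = fisher_z_weight(y, mag), z_par = NA_real_),
      class = "slope_estimate"
    )
  )
}

#' Group-mean dRT curve fit and adjusted R-squared
#'
#' Averages the per-participant dRT profiles digit-wise and fits the chosen
#' magnitude model to the 8 group-mean points, returning the adjusted
#' R-squared `1 - (1 - R^2)(n - 1)/(n - p - 1)` with n = 8.
#'
#' @param profiles List of `drt_profile` objects (>= 2).
#' @param model `"categorical"` or `"continuous"`.
#' @return List with `mean_drt` (named numeric), `model`, `r_squared`,
#'   `adj_r_squared`, `coefficients`.
#' @export
group_curve_fit <- function(profiles, model = c("categorical", "continuous")) {
  model <- match.arg(model)
  if (length(profiles) < 2) stop("need at least 2 profiles")
  digits <- profiles[[1]]$digits
  mat <- vapply(profiles, function(p) p$drt, numeric(length(digits)))
  y <- rowMeans(mat)
  x <- if (model == "categorical") ifelse(digits > 5, 0.5, -0.5) else digits
  n <- length(y)
  p <- 1L
  if (n < p + 2L) stop("too few points for adjusted R-squared")
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(mean_drt = stats::setNames(y, digits), model = model,
       r_squared = r2, adj_r_squared = adj,
       coefficients = stats::coef(fit))
}

#' Estimate all slopes for a preprocessed study
#'
#' Runs [compute_drt()] and the task-appropriate slope models for every
#' included participant and task, producing the tidy per-participant slope
#' table consumed by the group-inference and bootstrap stages.
#'
#' @param retained_trials Retained trials from [preprocess_study()],
#'   already restricted to included participants.
#' @param digits Digit set of the design.
#' @return Data frame with one row per participant x model: columns
#'   `participant_id`, `group`, `task`, `model`, `b_mag`, `b_par`, `z_mag`,
#'   `z_par`, `intercept`.
#' @export
estimate_slopes <- function(retained_trials, digits = DIGITS) {
  key <- interaction(retained_trials$participant_id, retained_trials$task,
                     drop = TRUE)
  pieces <- split(retained_trials, key)
  rows <- lapply(pieces, function(tt) {
    prof <- compute_drt(tt, digits)
    ests <- if (tt$task[1] == "PJ") {
      list(fit_pj_model(prof))
    } else {
      fit_mc_models(prof)
    }
    do.call(rbind, lapply(ests, function(e) {
      data.frame(participant_id = tt$participant_id[1], group = tt$group[1],
                 task = e$task, model = e$model, b_mag = e$b_mag,
                 b_par = e$b_par, z_mag = e$z_mag, z_par = e$z_par,
                 intercept = e$intercept, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$participant_id, out$task, out$model), , drop = FALSE]
}
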