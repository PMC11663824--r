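#' Classify a slope against its null interval
#'
#' `reliable` when the empirical slope lies strictly below the 5th
#' percentile of the null distribution, `reliable_reverse` when strictly
#' above the 95th percentile, otherwise `unreliable` (boundary equality is
#' unreliable, matching the strict inequalities of the classification
#' rule).
#'
#' @param slope Empirical slope.
#' @param q05,q95 Null-distribution percentiles (`q05 <= q95`).
#' @return One of `"reliable"`, `"reliable_reverse"`, `"unreliable"`.
#' @export
classify_slope <- function(slope, q05, q95) {
  if (q05 > q95) stop("q05 must not exceed q95")
  if (slope < q05) "reliable"
  else if (slope > q95) "reliable_reverse"
  else "unreliable"
}

#' H0 bootstrap classification of individual SNARC/MARC effects
#'
#' Builds each participant's null slope distribution by severing the link
#' between response side and RT: per iteration and digit, two sets of
#' `set_size` RTs are drawn with replacement from that digit's pooled
#' retained RTs (both hands together); one set is treated as left-hand and
#' the other as right-hand responses, a dRT profile is formed, and the
#' task's slope model is fitted (parity judgment: magnitude + parity
#' regression, giving both a SNARC and a MARC null slope per iteration;
#' magnitude classification: categorical model).  The empirical slope is
#' classified against the 5th/95th percentiles (linear interpolation) of
#' the `n_iter` null slopes.
#'
#' @param trials Retained trials of one participant and one task.
#' @param n_iter Bootstrap iterations (default 5000).
#' @param set_size Responses per resampled hand set (default 20).
#' @param seed Integer seed.
#' @param digits Digit set of the design.
#' @return Data frame with one row per effect (`SNARC`, plus `MARC` for the
#'   parity task): `participant_id`, `task`, `effect`, `empirical_slope`,
#'   `q05`, `q95`, `n_iterations`, `label`.
#' @export
h0_bootstrap <- function(trials, n_iter = 5000, set_size = 20, seed = 1L,
                         digits = DIGITS) {
  task <- trials$task[1]
  pid <- trials$participant_id[1]
  pools <- lapply(digits, function(d) trials$rt_ms[trials$digit == d])
  empty <- vapply(pools, length, 0L) == 0
  if (any(empty)) {
    stop(sprintf("no retained trials for digit %d", digits[which(empty)[1]]))
  }
  set.seed(seed)
  drt_mat <- matrix(0, nrow = length(digits), ncol = n_iter)
  for (k in seq_along(digits)) {
    pool <- pools[[k]]
    right <- matrix(pool[sample.int(length(pool), set_size * n_iter,
                                    replace = TRUE)], nrow = set_size)
    left <- matrix(pool[sample.int(length(pool), set_size * n_iter,
                                   replace = TRUE)], nrow = set_size)
    drt_mat[k, ] <- .colMeans(right, set_size, n_iter) -
      .colMeans(left, set_size, n_iter)
  }

  prof <- compute_drt(trials, digits)
  if (task == "PJ") {
    x_mat <- cbind(1, digits, parity_contrast(digits))
    emp <- fit_pj_model(prof)
    emp_slopes <- c(SNARC = emp$b_mag, MARC = emp$b_par)
  } else {
    x_mat <- cbind(1, ifelse(digits > 5, 0.5, -0.5))
    emp <- fit_mc_models(prof)$categorical
    emp_slopes <- c(SNARC = emp$b_mag)
  }
  proj <- solve(crossprod(x_mat), t(x_mat))
  boot_coef <- proj %*% drt_mat  # p x n_iter

  rows <- lapply(names(emp_slopes), function(effect) {
    row_idx <- if (effect == "SNARC") 2L else 3L
    slopes <- boot_coef[row_idx, ]
    q <- stats::quantile(slopes, c(0.05, 0.95), names = FALSE, type = 7)
    data.frame(
      participant_id = pid, task = task, effect = effect,
      empirical_slope = unname(emp_slopes[[effect]]),
      q05 = q[1], q95 = q[2], n_iterations = n_iter,
      label = classify_slope(emp_slopes[[effect]], q[1], q[2]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' H0 bootstrap for every participant and task of a study
#'
#' Runs [h0_bootstrap()] for each participant x task with a per-participant
#' seed derived from the master seed, and attaches the group label.
#'
#' @param retained_trials Retained trials of the included participants.
#' @param n_iter,set_size See [h0_bootstrap()].
#' @param master_seed Master integer seed.
#' @return Data frame of classifications with a `group` column.
#' @export
bootstrap_study <- function(retained_trials, n_iter = 5000, set_size = 20,
                            master_seed = 1L) {
  key <- interaction(retained_trials$participant_id, retained_trials$task,
                     drop = TRUE)
  pieces <- split(retained_trials, key)
  rows <- lapply(pieces, function(tt) {
    seed <- derive_seed(master_seed,
                        paste0(tt$participant_id[1], "_boot_", tt$task[1]))
    cls <- h0_bootstrap(tt, n_iter = n_iter, set_size = set_size,
                        seed = seed)
    cls$group <- tt$group[1]
    cls
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$participant_id, out$task, out$effect), , drop = FALSE]
}

#' Prevalence contingency table of bootstrap classifications
#'
#' Cross-tabulates groups against the three reliability labels for one task
#' and effect.
#'
#' @param classifications Data frame from [bootstrap_study()] (already
#'   filtered to one task and effect).
#' @param groups Optional character vector fixing the group (row) order.
#' @return A list of class `prevalence_table`: `counts` (groups x labels
#'   integer matrix) and `percent`.
#' @export
prevalence_table <- function(classifications, groups = NULL) {
  if (is.null(groups)) groups <- unique(classifications$group)
  labels <- c("reliable", "reliable_reverse", "unreliable")
  counts <- table(factor(classifications$group, levels = groups),
                  factor(classifications$label, levels = labels))
  counts <- unclass(counts)
  if (any(rowSums(counts) == 0)) {
    empty <- rownames(counts)[rowSums(counts) == 0]
    stop(sprintf("group(s) with no classified participants: %s",
                 paste(empty, collapse = ", ")))
  }
  structure(
    list(counts = counts, percent = 100 * counts / rowSums(counts)),
    class = "prevalence_table"
  )
}

#' @export
print.prevalence_table <- function(x, ...) {
  out <- x$counts
  cat("Prevalence (counts):\n")
  print(out)
  cat("Percent:\n")
  print(round(x$percent, 2))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with `df = (r - 1)(c - 1)`; no continuity
#' correction.
#'
#' @param tab Numeric matrix of counts with positive row and column sums.
#' @return A [snarc_test()] of kind `chi_square`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all row and column sums must be positive")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  snarc_test("chi_square", stat, df,
             stats::pchisq(stat, df, lower.tail = FALSE),
             sidedness = "two", n = sum(tab))
}

# log multivariate hypergeometric probability of a table with fixed margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# Enumerate all r x c tables with the given margins, calling fn(tab) for
# each; aborts (returning NULL) once more than `cap` tables were visited.
enumerate_tables <- function(row_sums, col_sums, fn, cap = 1e6) {
  r <- length(row_sums)
  cc <- length(col_sums)
  tab <- matrix(0, r, cc)
  count <- 0L
  rec <- function(i, j, row_left, col_left) {
    if (count > cap) return(FALSE)
    if (i == r && j == cc) {
      v <- col_left[cc]
      if (v == row_left[r] && v >= 0) {
        tab[r, cc] <<- v
        count <<- count + 1L
        fn(tab)
      }
      return(TRUE)
    }
    if (j == cc) {  # last column of a non-final row is forced
      v <- row_left[i]
      if (v < 0 || v > col_left[cc]) return(TRUE)
      tab[i, j] <<- v
      col_left[cc] <- col_left[cc] - v
      return(rec(i + 1, 1, `[<-`(row_left, i, 0), col_left))
    }
    if (i == r) {  # last row: cells forced by column remainders
      v <- col_left[j]
      if (v < 0 || v > row_left[r]) return(TRUE)
      tab[i, j] <<- v
      return(rec(i, j + 1, `[<-`(row_left, r, row_left[r] - v), col_left))
    }
    hi <- min(row_left[i], col_left[j])
    for (v in 0:hi) {
      tab[i, j] <<- v
      ok <- rec(i, j + 1, `[<-`(row_left, i, row_left[i] - v),
                `[<-`(col_left, j, col_left[j] - v))
      if (!ok) return(FALSE)
    }
    TRUE
  }
  completed <- rec(1, 1, row_sums, col_sums)
  if (!completed) NULL else count
}

#' Fisher's exact test for r x c contingency tables
#'
#' The p-value is the total probability, under the multivariate
#' hypergeometric null with the observed margins, of all tables whose
#' probability does not exceed that of the observed table.  Exact
#' enumeration is used while the number of candidate tables stays within
#' `max_tables`; otherwise (or on request) the null is sampled with
#' `n_mc` Monte-Carlo tables drawn with fixed margins, using the add-one
#' permutation estimator.
#'
#' @param tab Numeric matrix of counts.
#' @param method `"auto"`, `"enumeration"` or `"monte_carlo"`.
#' @param n_mc Monte-Carlo tables (default 1e5).
#' @param seed Integer seed for the Monte-Carlo branch.
#' @param max_tables Enumeration cap (default 1e6).
#' @return A [snarc_test()] of kind `fisher_exact` (no statistic/df).
#' @export
fisher_exact_rxc <- function(tab, method = c("auto", "enumeration",
                                             "monte_carlo"),
                             n_mc = 1e5, seed = 1L, max_tables = 1e6) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("degenerate margins")
  lp_obs <- log_table_prob(tab)
  tol <- 1e-7
  if (method != "monte_carlo") {
    p_sum <- 0
    acc <- function(tt) {
      lp <- log_table_prob(tt)
      if (lp <= lp_obs + tol) p_sum <<- p_sum + exp(lp)
    }
    n_tab <- enumerate_tables(rs, cs, acc, cap = max_tables)
    if (!is.null(n_tab)) {
      res <- snarc_test("fisher_exact", NA_real_, NA_real_, min(p_sum, 1),
                        sidedness = "two", n = sum(tab))
      res$method <- "enumeration"
      res$n_tables <- n_tab
      return(res)
    }
    if (method == "enumeration") {
      stop(sprintf("more than %g tables; use method = 'monte_carlo'",
                   max_tables))
    }
  }
  set.seed(seed)
  sims <- stats::r2dtable(n_mc, rs, cs)
  lps <- vapply(sims, log_table_prob, 0)
  p <- (1 + sum(lps <= lp_obs + tol)) / (n_mc + 1)
  res <- snarc_test("fisher_exact", NA_real_, NA_real_, p,
                    sidedness = "two", n = sum(tab))
  res$method <- "monte_carlo"
  res$n_mc <- n_mc
  res
}
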