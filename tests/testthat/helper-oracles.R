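# Independent oracles and fixture builders shared across the test files.

# Brute-force OLS via the normal equations (independent of lm()).
ols_oracle <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Construct a vector of length n with exactly the requested mean and SD
# (n-1 denominator), so summary-based and raw-based tests must agree.
exact_moment_vector <- function(n, mean, sd) {
  base <- seq_len(n)
  z <- (base - mean(base)) / stats::sd(base)
  mean + sd * z
}

# Jonckheere-Terpstra statistic, computed naively by pair counting.
jt_naive <- function(values, groups, order) {
  g <- factor(as.character(groups), levels = order)
  pieces <- split(values, g)
  tot <- 0
  k <- length(pieces)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      for (x in pieces[[i]]) {
        tot <- tot + sum(x < pieces[[j]]) + 0.5 * sum(x == pieces[[j]])
      }
    }
  }
  tot
}

# Exact permutation null of the JT statistic by full enumeration of all
# distinct assignments of the label multiset; returns the one-sided
# (increasing) p-value: the proportion of assignments with T >= observed.
jt_enum_pvalue <- function(values, groups, order) {
  g <- as.character(groups)
  t_obs <- jt_naive(values, g, order)
  n <- length(values)
  labels <- sort(g)
  stats_all <- numeric(0)
  rec <- function(remaining, acc) {
    if (length(remaining) == 0) {
      stats_all[length(stats_all) + 1] <<- jt_naive(values, acc, order)
      return(invisible())
    }
    for (lab in unique(remaining)) {
      rec(remaining[-match(lab, remaining)], c(acc, lab))
    }
  }
  rec(labels, character(0))
  mean(stats_all >= t_obs - 1e-9)
}

# Minimal complete trial set: one participant/task, each digit on both
# sides, with caller-supplied RTs (recycled).
make_cell_trials <- function(rt_left, rt_right, task = "PJ", pid = "p1",
                             group = "g") {
  digits <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L)
  nl <- length(rt_left)
  nr <- length(rt_right)
  data.frame(
    participant_id = pid, group = group, task = task,
    block = 1L, trial_index = seq_len(8 * (nl + nr)),
    digit = c(rep(digits, each = nl), rep(digits, each = nr)),
    response_side = c(rep("left", 8 * nl), rep("right", 8 * nr)),
    correct = TRUE,
    rt_ms = c(rep(rt_left, times = 8), rep(rt_right, times = 8)),
    stringsAsFactors = FALSE
  )
}

# Bare trial frame for filter tests (single participant/task).
make_trials <- function(rt, correct = TRUE, task = "PJ", pid = "p1") {
  n <- length(rt)
  data.frame(
    participant_id = rep(pid, n), group = rep("g", n),
    task = rep(task, n), block = rep(1L, n),
    trial_index = seq_len(n), digit = rep(c(1L, 2L), length.out = n),
    response_side = rep(c("left", "right"), length.out = n),
    correct = rep(correct, length.out = n), rt_ms = rt,
    stringsAsFactors = FALSE
  )
}

quiet_cfg <- function(label = "g", n = 2, slope_mean = -6, slope_sd = 4, ...) {
  group_config(label, n, slope_mean, slope_sd, ...)
}
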