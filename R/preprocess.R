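#' Sequential trial filtering for one participant and task
#'
#' Applies the preregistered filtering cascade, in order: (1) incorrect
#' responses are dropped; (2) RTs below/above the analysis window (default
#' 200--1500 ms) are dropped; (3) trials with RTs outside mean +/- k*SD of
#' the currently retained trials (mean and SD pooled over the whole task)
#' are dropped, and this trimming pass is repeated until the retained set
#' no longer changes.  SD uses the n-1 denominator.
#'
#' @param trials Data frame of trials for a single participant and task.
#' @param rt_window Numeric length-2 lower/upper bound in ms.
#' @param sd_multiplier Trimming multiplier `k` (default 3).
#' @param max_iter Hard cap on trimming passes (default 100; the loop
#'   always terminates because the retained set strictly shrinks).
#' @return A list with `trials` (the retained rows) and `report`, a one-row
#'   data frame with `n_input`, `n_removed_incorrect`, `n_removed_window`,
#'   `n_removed_sd`, `n_retained`, `retention_fraction` and
#'   `sd_iterations` (the number of passes run, counting the final
#'   no-change pass).
#' @export
filter_trials <- function(trials, rt_window = c(200, 1500),
                          sd_multiplier = 3, max_iter = 100) {
  n_input <- nrow(trials)
  if (n_input == 0) {
    report <- data.frame(
      n_input = 0L, n_removed_incorrect = 0L, n_removed_window = 0L,
      n_removed_sd = 0L, n_retained = 0L, retention_fraction = 0,
      sd_iterations = 0L
    )
    return(list(trials = trials, report = report))
  }
  if (length(unique(trials$participant_id)) > 1 ||
      length(unique(trials$task)) > 1) {
    stop("filter_trials expects trials of a single participant and task")
  }
  keep <- as.logical(trials$correct)
  n_removed_incorrect <- sum(!keep)
  cur <- trials[keep, , drop = FALSE]

  in_window <- cur$rt_ms >= rt_window[1] & cur$rt_ms <= rt_window[2]
  n_removed_window <- sum(!in_window)
  cur <- cur[in_window, , drop = FALSE]

  n_removed_sd <- 0L
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    if (nrow(cur) < 2) break
    m <- mean(cur$rt_ms)
    s <- stats::sd(cur$rt_ms)
    ok <- abs(cur$rt_ms - m) <= sd_multiplier * s
    if (all(ok) || iterations >= max_iter) break
    n_removed_sd <- n_removed_sd + sum(!ok)
    cur <- cur[ok, , drop = FALSE]
  }

  report <- data.frame(
    n_input = n_input,
    n_removed_incorrect = n_removed_incorrect,
    n_removed_window = n_removed_window,
    n_removed_sd = n_removed_sd,
    n_retained = nrow(cur),
    retention_fraction = nrow(cur) / n_input,
    sd_iterations = iterations
  )
  list(trials = cur, report = report)
}

#' Filter a whole study's trials participant- and task-wise
#'
#' @param trials Data frame of all trials.
#' @inheritParams filter_trials
#' @return A list with `trials` (retained rows) and `reports` (one row per
#'   participant x task, with `participant_id`, `group`, `task` prepended
#'   to the [filter_trials()] report columns).
#' @export
preprocess_study <- function(trials, rt_window = c(200, 1500),
                             sd_multiplier = 3, max_iter = 100) {
  key <- interaction(trials$participant_id, trials$task, drop = TRUE)
  pieces <- split(trials, key)
  kept <- vector("list", length(pieces))
  reps <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    res <- filter_trials(pieces[[i]], rt_window, sd_multiplier, max_iter)
    kept[[i]] <- res$trials
    reps[[i]] <- cbind(
      data.frame(participant_id = pieces[[i]]$participant_id[1],
                 group = pieces[[i]]$group[1],
                 task = pieces[[i]]$task[1],
                 stringsAsFactors = FALSE),
      res$report
    )
  }
  list(
    trials = do.call(rbind, c(kept, make.row.names = FALSE)),
    reports = do.call(rbind, c(reps, make.row.names = FALSE))
  )
}

#' Participant-level exclusion decisions
#'
#' A participant is excluded when, in either task, (a) fewer than
#' `retention_threshold` (default 75%) of the task's trials survived the
#' filtering cascade (`low_retention`, checked first), or (b) any
#' digit x response-side cell has no retained trial, which would make the
#' magnitude x side slope incomputable (`empty_cell`).  A missing task also
#' counts as `empty_cell`.
#'
#' @param reports Per participant x task filter reports from
#'   [preprocess_study()].
#' @param retained_trials The retained trials from [preprocess_study()].
#' @param retention_threshold Minimum retained fraction (default 0.75).
#' @param tasks Tasks that must be present (default `c("PJ", "MC")`).
#' @param digits Digit set of the design.
#' @return Data frame with `participant_id`, `excluded`, `reason`
#'   (`low_retention`, `empty_cell` or `none`).
#' @export
exclude_participants <- function(reports, retained_trials,
                                 retention_threshold = 0.75,
                                 tasks = TASKS, digits = DIGITS) {
  ids <- unique(reports$participant_id)
  out <- lapply(ids, function(pid) {
    rep_p <- reports[reports$participant_id == pid, , drop = FALSE]
    reason <- "none"
    if (any(rep_p$retention_fraction < retention_threshold)) {
      reason <- "low_retention"
    } else if (!all(tasks %in% rep_p$task)) {
      reason <- "empty_cell"
    } else {
      tr_p <- retained_trials[retained_trials$participant_id == pid, ,
                              drop = FALSE]
      for (task in tasks) {
        tt <- tr_p[tr_p$task == task, , drop = FALSE]
        cells <- table(factor(tt$digit, levels = digits),
                       factor(tt$response_side, levels = c("left", "right")))
        if (any(cells == 0)) {
          reason <- "empty_cell"
          break
        }
      }
    }
    data.frame(participant_id = pid, excluded = reason != "none",
               reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
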