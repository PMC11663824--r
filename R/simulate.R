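#' Simulate one participant's trial data for both tasks
#'
#' Draws the participant's true effect parameters from the group
#' distributions and generates the full two-task design: per task, 2 blocks
#' x 8 digits x 20 repetitions = 320 trials in randomized order within
#' block.  The response-to-key mapping reverses between blocks (parity
#' judgment: odd-left/even-right in block 1; magnitude classification:
#' small-left/large-right in block 1), so every digit is answered with both
#' hands across blocks.
#'
#' RTs follow an ex-Gaussian: a Gaussian component centred on the
#' participant baseline plus an exponential tail.  Half of the
#' side-dependent effect is added to right-hand responses and subtracted
#' from left-hand responses, so the expected right-minus-left dRT for digit
#' `d` is exactly `a + b*d + m*c(d)` with `c(d)` the -0.5/+0.5 parity
#' contrast.  Error trials are flagged (not removed) and their response
#' lands on the wrong side; lapse trials get an RT drawn outside the
#' 200--1500 ms window.
#'
#' @param config A [group_config()] object.
#' @param participant_id Identifier for the participant.
#' @param seed Integer seed; the simulation is fully deterministic given
#'   `(config, participant_id, seed)`.
#' @return A data frame of trials with columns `participant_id`, `group`,
#'   `task`, `block`, `trial_index`, `digit`, `response_side`, `correct`,
#'   `rt_ms`, and an attribute `params` holding the drawn true parameters
#'   (`pj_slope`, `mc_slope`, `marc`, `pj_intercept`, `mc_intercept`,
#'   `base_rt`).
#' @export
simulate_participant <- function(config, participant_id, seed) {
  validate_group_config(config)
  set.seed(seed)
  params <- list(
    pj_slope = stats::rnorm(1, config$slope_mean, config$slope_sd),
    mc_slope = stats::rnorm(1, config$mc_slope_mean, config$mc_slope_sd),
    marc = stats::rnorm(1, config$marc_mean, config$marc_sd),
    pj_intercept = stats::rnorm(1, config$drt_intercept_mean,
                                config$drt_intercept_sd),
    mc_intercept = stats::rnorm(1, config$drt_intercept_mean,
                                config$drt_intercept_sd),
    base_rt = stats::rnorm(1, config$base_rt_mean, config$base_rt_sd_between)
  )
  out <- lapply(TASKS, function(task) {
    simulate_task(config, participant_id, task, params)
  })
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  attr(trials, "params") <- params
  trials
}

simulate_task <- function(config, participant_id, task, params) {
  n_rep <- 20L
  blocks <- lapply(1:2, function(block) {
    digit <- sample(rep(DIGITS, n_rep))
    n <- length(digit)
    parity_c <- ifelse(digit %% 2 == 0, 0.5, -0.5)
    if (task == "PJ") {
      eff <- params$pj_intercept + params$pj_slope * digit +
        params$marc * parity_c
      # block 1: odd -> left, even -> right; block 2 reversed
      required_right <- if (block == 1L) digit %% 2 == 0 else digit %% 2 == 1
    } else {
      eff <- params$mc_intercept + params$mc_slope * digit +
        params$marc * parity_c
      # block 1: small -> left, large -> right; block 2 reversed
      required_right <- if (block == 1L) digit > 5 else digit < 5
    }
    correct <- stats::runif(n) >= config$error_rate
    responded_right <- ifelse(correct, required_right, !required_right)
    side_sign <- ifelse(responded_right, 1, -1)
    rt <- params$base_rt + config$block_effect * (block == 2L) +
      0.5 * side_sign * eff +
      stats::rnorm(n, 0, config$noise_sd_within)
    if (config$exgauss_tau > 0) {
      rt <- rt + stats::rexp(n, rate = 1 / config$exgauss_tau)
    }
    lapse <- stats::runif(n) < config$lapse_rate
    if (any(lapse)) {
      nl <- sum(lapse)
      low <- stats::runif(nl) < 0.5
      rt[lapse] <- ifelse(low,
                          stats::runif(nl, 50, 195),
                          stats::runif(nl, 1505, 2600))
    }
    data.frame(
      participant_id = as.character(participant_id),
      group = config$group_label,
      task = task,
      block = block,
      trial_index = seq_len(n),
      digit = digit,
      response_side = ifelse(responded_right, "right", "left"),
      correct = correct,
      rt_ms = pmax(rt, 1),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, blocks)
}

#' Simulate a full multi-group study
#'
#' Simulates every participant of every group (with per-participant seeds
#' derived from the master seed via [derive_seed()]) and draws each
#' participant's questionnaire responses item-wise from the group's
#' `cdpq_item_probs`.
#'
#' @param configs List of [group_config()] objects with distinct labels.
#' @param seed Master integer seed.
#' @return A list with elements `trials` (all trials), `cdpq` (one row per
#'   participant with raw item tokens `item1`..`item7`), and `params` (one
#'   row per participant with the true generative parameters).
#' @export
simulate_study <- function(configs, seed) {
  if (length(configs) < 1) stop("at least one group config required")
  labs <- vapply(configs, `[[`, "", "group_label")
  if (anyDuplicated(labs)) stop("duplicate group labels")
  trial_list <- list()
  cdpq_list <- list()
  param_list <- list()
  for (cfg in configs) {
    validate_group_config(cfg)
    for (i in seq_len(cfg$n_participants)) {
      pid <- sprintf("%s_%03d", cfg$group_label, i)
      pseed <- derive_seed(seed, pid)
      tr <- simulate_participant(cfg, pid, pseed)
      pars <- attr(tr, "params")
      attr(tr, "params") <- NULL
      trial_list[[pid]] <- tr
      cdpq_list[[pid]] <- simulate_cdpq(cfg, pid,
                                        derive_seed(seed,
                                                    paste0(pid, "_cdpq")))
      param_list[[pid]] <- data.frame(
        participant_id = pid, group = cfg$group_label,
        pj_slope = pars$pj_slope, mc_slope = pars$mc_slope,
        marc = pars$marc, pj_intercept = pars$pj_intercept,
        mc_intercept = pars$mc_intercept, base_rt = pars$base_rt,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    trials = do.call(rbind, c(trial_list, make.row.names = FALSE)),
    cdpq = do.call(rbind, c(cdpq_list, make.row.names = FALSE)),
    params = do.call(rbind, c(param_list, make.row.names = FALSE))
  )
}

#' Draw one participant's questionnaire responses
#'
#' Samples each of the 7 items independently from the group's
#' `cdpq_item_probs` row (columns LR / NONE / RL).
#'
#' @param config A [group_config()] object.
#' @param participant_id Identifier.
#' @param seed Integer seed.
#' @return One-row data frame in the CDPQ CSV format.
#' @export
simulate_cdpq <- function(config, participant_id, seed) {
  set.seed(seed)
  tok <- c("LR", "NONE", "RL")
  items <- vapply(1:7, function(j) {
    sample(tok, 1, prob = config$cdpq_item_probs[j, ])
  }, "")
  out <- data.frame(participant_id = as.character(participant_id),
                    group = config$group_label, stringsAsFactors = FALSE)
  for (j in 1:7) out[[paste0("item", j)]] <- items[j]
  out
}

#' Read / write the trial and questionnaire CSV formats
#'
#' The trial CSV has columns `participant_id`, `group`, `task`, `block`,
#' `trial_index`, `digit`, `response_side`, `correct`, `rt_ms` (UTF-8,
#' comma-separated, header required).  The questionnaire CSV has
#' `participant_id`, `group`, `item1`..`item7` and optional pass-through
#' columns (e.g. finger-counting `start_hand`, `stability`).
#'
#' @param trials,cdpq Data frames in the respective formats.
#' @param path File path.
#' @return `read_*` return the data frame; `write_*` return the path
#'   invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "task", "block", "trial_index",
            "digit", "response_side", "correct", "rt_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("malformed trial CSV '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  df$participant_id <- as.character(df$participant_id)
  df$correct <- as.logical(df$correct)
  df
}

#' @rdname write_trials_csv
#' @export
write_cdpq_csv <- function(cdpq, path) {
  utils::write.csv(cdpq, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_cdpq_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", paste0("item", 1:7))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("malformed CDPQ CSV '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  df$participant_id <- as.character(df$participant_id)
  df
}
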