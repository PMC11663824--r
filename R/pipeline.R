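#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> filter -> exclude -> estimate ->
#' group inference -> H0 bootstrap -> questionnaire scoring, and writes
#' every report table as CSV plus a machine-readable `summary.json` to the
#' configured output directory.  The report layer only formats results; all
#' numbers are produced by the stage functions.
#'
#' Output files: `trials.csv`, `cdpq.csv`, `true_params.csv` (simulation
#' runs only), `filter_reports.csv`, `exclusions.csv`,
#' `retained_trials.csv`, `slopes.csv`, `group_tests.csv`,
#' `trend_tests.csv`, `task_comparison.csv`, `classifications.csv`,
#' `prevalence_<task>_<effect>.csv`, `prevalence_tests.csv`,
#' `cdpq_scored.csv`, `cdpq_item_tests.csv`, `cdpq_trend.csv`,
#' `cdpq_slope_cor.csv`, `summary.json`.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with every intermediate product.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  # --- data ----------------------------------------------------------------
  if (!is.null(config$groups)) {
    study <- simulate_study(config$groups, config$master_seed)
    trials <- study$trials
    cdpq <- study$cdpq
    write_trials_csv(trials, path("trials.csv"))
    write_cdpq_csv(cdpq, path("cdpq.csv"))
    utils::write.csv(study$params, path("true_params.csv"),
                     row.names = FALSE)
    group_order <- vapply(config$groups, `[[`, "", "group_label")
  } else {
    if (is.null(config$trials_file)) {
      stop("run_config needs either 'groups' or 'trials_file'")
    }
    trials <- read_trials_csv(config$trials_file)
    cdpq <- if (!is.null(config$cdpq_file)) {
      read_cdpq_csv(config$cdpq_file)
    } else {
      NULL
    }
    group_order <- unique(trials$group)
  }

  # --- preprocessing -------------------------------------------------------
  prep <- preprocess_study(trials, rt_window = config$rt_window,
                           sd_multiplier = config$sd_multiplier)
  decisions <- exclude_participants(prep$reports, prep$trials,
                                    retention_threshold =
                                      config$retention_threshold)
  included <- decisions$participant_id[!decisions$excluded]
  retained <- prep$trials[prep$trials$participant_id %in% included, ,
                          drop = FALSE]
  utils::write.csv(prep$reports, path("filter_reports.csv"),
                   row.names = FALSE)
  utils::write.csv(decisions, path("exclusions.csv"), row.names = FALSE)
  write_trials_csv(retained, path("retained_trials.csv"))

  # --- slopes --------------------------------------------------------------
  slopes <- estimate_slopes(retained)
  utils::write.csv(slopes, path("slopes.csv"), row.names = FALSE)

  # --- group inference -----------------------------------------------------
  group_tests <- group_test_table(slopes, group_order, rscale = config$rscale)
  utils::write.csv(group_tests, path("group_tests.csv"), row.names = FALSE)
  trend <- trend_test_table(slopes, group_order, n_perm = config$n_perm,
                            master_seed = config$master_seed,
                            rscale = config$rscale)
  utils::write.csv(trend, path("trend_tests.csv"), row.names = FALSE)
  taskcmp <- task_comparison_table(slopes, rscale = config$rscale,
                                   cor_width = config$cor_bf_width)
  utils::write.csv(taskcmp, path("task_comparison.csv"), row.names = FALSE)

  # --- H0 bootstrap prevalence --------------------------------------------
  classifications <- bootstrap_study(retained, n_iter = config$n_boot,
                                     set_size = config$boot_set_size,
                                     master_seed = config$master_seed)
  utils::write.csv(classifications, path("classifications.csv"),
                   row.names = FALSE)
  prev_specs <- list(c("PJ", "SNARC"), c("MC", "SNARC"), c("PJ", "MARC"))
  prev_tests <- list()
  prevalences <- list()
  for (spec in prev_specs) {
    sub <- classifications[classifications$task == spec[1] &
                             classifications$effect == spec[2], ,
                           drop = FALSE]
    pt <- prevalence_table(sub, groups = group_order)
    key <- paste0(spec[1], "_", spec[2])
    prevalences[[key]] <- pt
    utils::write.csv(
      data.frame(group = rownames(pt$counts), pt$counts,
                 check.names = FALSE),
      path(sprintf("prevalence_%s_%s.csv", spec[1], spec[2])),
      row.names = FALSE
    )
    # small runs can leave a label column empty; the test drops it
    nonzero <- pt$counts[, colSums(pt$counts) > 0, drop = FALSE]
    ct <- chi_square_independence(nonzero)
    prev_tests[[key]] <- data.frame(
      task = spec[1], effect = spec[2], chi_square = ct$statistic,
      df = ct$df, p_value = ct$p_value, stringsAsFactors = FALSE
    )
  }
  prev_tests <- do.call(rbind, c(prev_tests, make.row.names = FALSE))
  utils::write.csv(prev_tests, path("prevalence_tests.csv"),
                   row.names = FALSE)

  # --- CDPQ ----------------------------------------------------------------
  cdpq_out <- NULL
  if (!is.null(cdpq)) {
    scored <- score_cdpq(cdpq[cdpq$participant_id %in% included, ,
                              drop = FALSE])
    utils::write.csv(scored, path("cdpq_scored.csv"), row.names = FALSE)
    item_tests <- lapply(1:7, function(i) {
      res <- item_contingency(scored, i, posthoc = FALSE,
                              seed = derive_seed(config$master_seed,
                                                 paste0("item", i)))
      data.frame(item = i, method = res$method,
                 statistic = res$test$statistic, df = res$test$df,
                 p_value = res$test$p_value, stringsAsFactors = FALSE)
    })
    item_tests <- do.call(rbind, item_tests)
    utils::write.csv(item_tests, path("cdpq_item_tests.csv"),
                     row.names = FALSE)
    cdpq_trend <- total_score_trend(scored, order = group_order,
                                    n_perm = config$n_perm,
                                    seed = derive_seed(config$master_seed,
                                                       "cdpq_trend"))
    utils::write.csv(
      data.frame(t_jt = cdpq_trend$statistic, p_value = cdpq_trend$p_value,
                 n_permutations = cdpq_trend$n_permutations),
      path("cdpq_trend.csv"), row.names = FALSE
    )
    slope_cor <- score_slope_correlation(scored, slopes,
                                         width = config$cor_bf_width)
    utils::write.csv(slope_cor, path("cdpq_slope_cor.csv"),
                     row.names = FALSE)
    cdpq_out <- list(scored = scored, item_tests = item_tests,
                     trend = cdpq_trend, slope_cor = slope_cor)
  }

  summary <- list(
    master_seed = config$master_seed,
    n_participants_input = length(unique(trials$participant_id)),
    n_excluded = sum(decisions$excluded),
    n_included = length(included),
    group_order = group_order,
    trend_tests = trend,
    prevalence_tests = prev_tests
  )
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    trials = trials, cdpq = cdpq, reports = prep$reports,
    decisions = decisions, retained = retained, slopes = slopes,
    group_tests = group_tests, trend_tests = trend,
    task_comparison = taskcmp, classifications = classifications,
    prevalences = prevalences, prevalence_tests = prev_tests,
    cdpq_results = cdpq_out, summary = summary
  ))
}

# Table-1/2 style layout: per group and measure, the one-sample test of the
# mean slope against zero.
group_test_table <- function(slopes, group_order, rscale = 0.707) {
  specs <- list(
    list(model = "pj_linear", col = "b_mag", measure = "SNARC", task = "PJ"),
    list(model = "pj_linear", col = "z_mag", measure = "standardized_SNARC",
         task = "PJ"),
    list(model = "pj_linear", col = "b_par", measure = "MARC", task = "PJ"),
    list(model = "pj_linear", col = "z_par", measure = "standardized_MARC",
         task = "PJ"),
    list(model = "mc_categorical", col = "b_mag", measure = "SNARC",
         task = "MC"),
    list(model = "mc_categorical", col = "z_mag",
         measure = "standardized_SNARC", task = "MC")
  )
  rows <- list()
  for (sp in specs) {
    sub <- slopes[slopes$model == sp$model, , drop = FALSE]
    for (g in group_order) {
      v <- sub[sub$group == g, sp$col]
      if (length(v) < 2) next
      res <- one_sample_t(v, rscale = rscale)
      rows[[length(rows) + 1]] <- data.frame(
        task = sp$task, measure = sp$measure, group = g, n = length(v),
        mean_slope = mean(v), sd_slope = stats::sd(v), t = res$statistic,
        df = res$df, p_value = res$p_value, bf10 = res$bf10,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Cross-sample comparisons: one-sided JT trend over the hypothesized group
# order plus one-sided Welch tests of consecutive group pairs.
trend_test_table <- function(slopes, group_order, n_perm = 2000,
                             master_seed = 1L, rscale = 0.707) {
  rows <- list()
  for (sp in list(c("pj_linear", "PJ"), c("mc_categorical", "MC"))) {
    sub <- slopes[slopes$model == sp[1], , drop = FALSE]
    jt <- jonckheere_terpstra(sub$b_mag, sub$group, order = group_order,
                              n_perm = n_perm,
                              seed = derive_seed(master_seed,
                                                 paste0("jt_", sp[2])))
    rows[[length(rows) + 1]] <- data.frame(
      task = sp[2], comparison = paste(group_order, collapse = " < "),
      test = "jt_trend", statistic = jt$statistic, df = NA_real_,
      p_value = jt$p_value, bf10 = NA_real_, stringsAsFactors = FALSE
    )
    for (i in seq_len(length(group_order) - 1)) {
      g1 <- group_order[i]
      g2 <- group_order[i + 1]
      res <- welch_t(sub$b_mag[sub$group == g1], sub$b_mag[sub$group == g2],
                     alternative = "less", rscale = rscale)
      rows[[length(rows) + 1]] <- data.frame(
        task = sp[2], comparison = paste(g1, "<", g2), test = "welch_t",
        statistic = res$statistic, df = res$df, p_value = res$p_value,
        bf10 = res$bf10, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Within-group PJ vs MC comparison on comparable (continuous) slopes and
# the between-task slope correlation (PJ linear vs MC categorical).
task_comparison_table <- function(slopes, rscale = 0.707, cor_width = 1 / 3) {
  pj <- slopes[slopes$model == "pj_linear", c("participant_id", "group",
                                              "b_mag")]
  mc_cont <- slopes[slopes$model == "mc_continuous",
                    c("participant_id", "b_mag")]
  mc_cat <- slopes[slopes$model == "mc_categorical",
                   c("participant_id", "b_mag")]
  m1 <- merge(pj, mc_cont, by = "participant_id",
              suffixes = c("_pj", "_mc"))
  m2 <- merge(pj, mc_cat, by = "participant_id", suffixes = c("_pj", "_mc"))
  rows <- lapply(unique(pj$group), function(g) {
    d1 <- m1[m1$group == g, , drop = FALSE]
    d2 <- m2[m2$group == g, , drop = FALSE]
    tt <- paired_t(d1$b_mag_pj, d1$b_mag_mc, rscale = rscale)
    cc <- pearson_cor(d2$b_mag_pj, d2$b_mag_mc, width = cor_width)
    data.frame(group = g, n = nrow(d1),
               paired_t = tt$statistic, paired_df = tt$df,
               paired_p = tt$p_value, paired_bf10 = tt$bf10,
               cor_r = cc$estimate, cor_p = cc$p_value, cor_bf10 = cc$bf10,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess`, `slopes`, `infer`, `bootstrap`,
#' `cdpq`, `all`.  All stages read and write CSV files under `--out`;
#' `simulate` and `all` need a `--config` JSON with simulation groups.
#' A ready-to-run launcher script is installed at
#' `system.file("cli", "snarc_pipeline.R", package = "snarcpipe")`.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the result of the executed stage.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    stop("usage: <simulate|preprocess|slopes|infer|bootstrap|cdpq|all> ",
         "[--config FILE] [--seed N] [--out DIR] [--n-boot N] [--n-perm N]")
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--n-boot", dest = "n_boot", type = "integer",
                          default = NULL),
    optparse::make_option("--n-perm", dest = "n_perm", type = "integer",
                          default = NULL)
  ))
  opts <- optparse::parse_args(parser, args = args[-1])

  cfg <- if (!is.null(opts$config)) {
    read_run_config(opts$config)
  } else {
    run_config()
  }
  if (!is.null(opts$seed)) cfg$master_seed <- opts$seed
  if (!is.null(opts$n_boot)) cfg$n_boot <- opts$n_boot
  if (!is.null(opts$n_perm)) cfg$n_perm <- opts$n_perm
  cfg$out_dir <- opts$out
  path <- function(f) file.path(cfg$out_dir, f)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  res <- switch(
    cmd,
    all = run_pipeline(cfg),
    simulate = {
      if (is.null(cfg$groups)) stop("simulate needs a config with 'groups'")
      study <- simulate_study(cfg$groups, cfg$master_seed)
      write_trials_csv(study$trials, path("trials.csv"))
      write_cdpq_csv(study$cdpq, path("cdpq.csv"))
      utils::write.csv(study$params, path("true_params.csv"),
                       row.names = FALSE)
      study
    },
    preprocess = {
      trials <- read_trials_csv(path("trials.csv"))
      prep <- preprocess_study(trials, rt_window = cfg$rt_window,
                               sd_multiplier = cfg$sd_multiplier)
      decisions <- exclude_participants(prep$reports, prep$trials,
                                        cfg$retention_threshold)
      included <- decisions$participant_id[!decisions$excluded]
      retained <- prep$trials[prep$trials$participant_id %in% included, ,
                              drop = FALSE]
      utils::write.csv(prep$reports, path("filter_reports.csv"),
                       row.names = FALSE)
      utils::write.csv(decisions, path("exclusions.csv"), row.names = FALSE)
      write_trials_csv(retained, path("retained_trials.csv"))
      list(reports = prep$reports, decisions = decisions,
           retained = retained)
    },
    slopes = {
      retained <- read_trials_csv(path("retained_trials.csv"))
      slopes <- estimate_slopes(retained)
      utils::write.csv(slopes, path("slopes.csv"), row.names = FALSE)
      slopes
    },
    infer = {
      slopes <- utils::read.csv(path("slopes.csv"),
                                stringsAsFactors = FALSE)
      group_order <- unique(slopes$group)
      gt <- group_test_table(slopes, group_order, rscale = cfg$rscale)
      tr <- trend_test_table(slopes, group_order, n_perm = cfg$n_perm,
                             master_seed = cfg$master_seed,
                             rscale = cfg$rscale)
      tc <- task_comparison_table(slopes, rscale = cfg$rscale,
                                  cor_width = cfg$cor_bf_width)
      utils::write.csv(gt, path("group_tests.csv"), row.names = FALSE)
      utils::write.csv(tr, path("trend_tests.csv"), row.names = FALSE)
      utils::write.csv(tc, path("task_comparison.csv"), row.names = FALSE)
      list(group_tests = gt, trend_tests = tr, task_comparison = tc)
    },
    bootstrap = {
      retained <- read_trials_csv(path("retained_trials.csv"))
      cls <- bootstrap_study(retained, n_iter = cfg$n_boot,
                             set_size = cfg$boot_set_size,
                             master_seed = cfg$master_seed)
      utils::write.csv(cls, path("classifications.csv"), row.names = FALSE)
      cls
    },
    cdpq = {
      cdpq <- read_cdpq_csv(path("cdpq.csv"))
      scored <- score_cdpq(cdpq)
      utils::write.csv(scored, path("cdpq_scored.csv"), row.names = FALSE)
      scored
    },
    stop(sprintf("unknown subcommand '%s'", cmd))
  )
  invisible(res)
}
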