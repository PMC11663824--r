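#' Score the 7-item directional-preferences questionnaire
#'
#' Each item response is reduced to one of three codes: `LR` (left-to-right
#' preference, scored -1), `RL` (right-to-left, scored +1) and `NONE`
#' (mixed order for the two ordering items, "no preference" for the rest,
#' scored 0).  The total is the sum over the seven items, spanning -7
#' (very strong LR preference) to +7 (very strong RL preference).
#'
#' Accepted raw tokens (case-insensitive): `LR`; `RL`; and `NONE`, `NP`,
#' `MIXED` or `NO_PREFERENCE` for the zero code.  For the two ordering
#' items (object naming, timeline) any non-monotone pattern should be
#' pre-coded as `MIXED` by the data source; the scorer treats all zero-code
#' tokens identically.
#'
#' @param responses Character vector of exactly 7 raw item tokens.
#' @return A list of class `cdpq_record`: `item_codes` (length-7 character)
#'   and `sum_score` (integer in `[-7, 7]`).
#' @export
score_cdpq_record <- function(responses) {
  if (length(responses) != 7) stop("exactly 7 item responses required")
  codes <- vapply(responses, normalize_cdpq_token, "", USE.NAMES = FALSE)
  score <- sum(ifelse(codes == "LR", -1L, ifelse(codes == "RL", 1L, 0L)))
  structure(list(item_codes = codes, sum_score = score),
            class = "cdpq_record")
}

normalize_cdpq_token <- function(token) {
  t <- toupper(trimws(as.character(token)))
  if (t == "LR") return("LR")
  if (t == "RL") return("RL")
  if (t %in% c("NONE", "NP", "MIXED", "NO_PREFERENCE")) return("NONE")
  stop(sprintf("unknown CDPQ response token '%s'", token))
}

#' Score a questionnaire data frame
#'
#' Applies [score_cdpq_record()] row-wise to a data frame in the CDPQ CSV
#' format (`participant_id`, `group`, `item1`..`item7`, plus optional
#' pass-through columns which are preserved).
#'
#' @param cdpq Data frame of raw responses.
#' @return The input with items replaced by normalized codes and a
#'   `sum_score` column appended.
#' @export
score_cdpq <- function(cdpq) {
  items <- paste0("item", 1:7)
  miss <- setdiff(items, names(cdpq))
  if (length(miss)) {
    stop(sprintf("missing item column(s): %s", paste(miss, collapse = ", ")))
  }
  out <- cdpq
  sums <- integer(nrow(cdpq))
  for (i in seq_len(nrow(cdpq))) {
    rec <- score_cdpq_record(unlist(cdpq[i, items], use.names = FALSE))
    out[i, items] <- as.list(rec$item_codes)
    sums[i] <- rec$sum_score
  }
  out$sum_score <- sums
  out
}

#' Per-item group x directionality contingency analysis
#'
#' Builds the groups x {LR, NONE, RL} table for one item and tests
#' independence with a Pearson chi-square, automatically switching to
#' Fisher's exact test when any expected cell frequency is below 5.
#' Optionally adds pairwise group comparisons (on the pairwise sub-tables,
#' same chi-square/Fisher switch) with Bonferroni-adjusted p-values.
#'
#' @param scored Scored questionnaire data frame from [score_cdpq()].
#' @param item Item number (1--7).
#' @param posthoc Run pairwise group comparisons? (default TRUE).
#' @param seed Seed for a Monte-Carlo Fisher fallback on large tables.
#' @return List with `table` (counts), `test` (a [snarc_test()]), `method`,
#'   and (if requested) `posthoc`, a data frame of pairwise comparisons
#'   with raw and Bonferroni-adjusted p-values.
#' @export
item_contingency <- function(scored, item, posthoc = TRUE, seed = 1L) {
  col <- paste0("item", item)
  if (!col %in% names(scored)) stop(sprintf("no column '%s'", col))
  tok <- scored[[col]]
  if (all(is.na(tok)) || length(tok) == 0) stop("empty item column")
  groups <- unique(scored$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  tab <- table(factor(scored$group, levels = groups),
               factor(tok, levels = c("LR", "NONE", "RL")))
  tab <- unclass(tab)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  test <- contingency_auto(tab, seed)
  out <- list(table = tab, test = test$test, method = test$method)
  if (posthoc) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    ph <- lapply(pairs, function(pr) {
      sub <- tab[pr, , drop = FALSE]
      sub <- sub[, colSums(sub) > 0, drop = FALSE]
      res <- contingency_auto(sub, seed)
      data.frame(group1 = pr[1], group2 = pr[2], method = res$method,
                 p_value = res$test$p_value, stringsAsFactors = FALSE)
    })
    ph <- do.call(rbind, ph)
    ph$p_adjusted <- pmin(1, ph$p_value * nrow(ph))  # Bonferroni
    out$posthoc <- ph
  }
  out
}

# chi-square with automatic Fisher switch on low expected frequencies
contingency_auto <- function(tab, seed = 1L) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(test = fisher_exact_rxc(tab, method = "auto", seed = seed),
         method = "fisher_exact")
  } else {
    list(test = chi_square_independence(tab), method = "chi_square")
  }
}

#' Trend test on questionnaire total scores
#'
#' Delegates to [jonckheere_terpstra()] on the per-participant sum scores,
#' one-sided for an increasing trend along the hypothesized group order.
#'
#' @param scored Scored questionnaire data frame from [score_cdpq()].
#' @param order Hypothesized group order (increasing).
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @param alternative Passed to [jonckheere_terpstra()].
#' @return A [snarc_test()] of kind `jt_trend`.
#' @export
total_score_trend <- function(scored, order, n_perm = 2000, seed = 1L,
                              alternative = "increasing") {
  jonckheere_terpstra(scored$sum_score, scored$group, order = order,
                      n_perm = n_perm, alternative = alternative,
                      seed = seed)
}

#' Correlation between questionnaire scores and SNARC slopes
#'
#' Matches participants between the scored questionnaire and a slope table
#' and computes, per group and task/model, the Pearson correlation of the
#' unstandardized slope with the total score (with default Bayes factor).
#'
#' @param scored Scored questionnaire data frame from [score_cdpq()].
#' @param slopes Slope table from [estimate_slopes()].
#' @param model Which slope model to correlate (default `"pj_linear"`).
#' @param width Prior width for the correlation Bayes factor.
#' @return Data frame with one row per group: `group`, `n`, `r`, `p_value`,
#'   `bf10`.
#' @export
score_slope_correlation <- function(scored, slopes, model = "pj_linear",
                                    width = 1 / 3) {
  sl <- slopes[slopes$model == model, , drop = FALSE]
  merged <- merge(scored[, c("participant_id", "group", "sum_score")],
                  sl[, c("participant_id", "b_mag")],
                  by = "participant_id")
  rows <- lapply(split(merged, merged$group), function(gd) {
    if (nrow(gd) < 3) stop("fewer than 3 matched pairs in a group")
    res <- pearson_cor(gd$sum_score, gd$b_mag, width = width)
    data.frame(group = gd$group[1], n = nrow(gd), r = res$estimate,
               p_value = res$p_value, bf10 = res$bf10,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
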