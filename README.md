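# snarcpipe

A tested, reusable R implementation of the statistical pipeline used in
cross-cultural studies of the SNARC effect (Spatial-Numerical Association
of Response Codes: smaller numbers are answered faster with the left hand,
larger numbers with the right) and the MARC effect (odd/even numbers are
answered faster with the left/right hand). It is aimed at numerical
cognition researchers who want to run, audit, or power-simulate this kind
of individual-differences RT analysis without re-deriving every stage.

## What it computes

For two binary-response tasks — parity judgment (PJ) and magnitude
classification (MC), each 2 blocks x 8 digits (1–9 without 5) x 20
repetitions per participant — the pipeline:

1. **Simulates** trial-level data (`simulate_study()`): per-participant
   true slopes drawn from group distributions, ex-Gaussian RT noise,
   configurable error and lapse rates, plus 7-item directional-preference
   questionnaire (CDPQ) responses.
2. **Filters** trials (`filter_trials()`): drop errors, drop RTs outside
   200–1500 ms, then iteratively trim RTs outside mean ± 3 SD until the
   retained set stabilizes; participants with < 75% valid trials or an
   empty digit x side cell are excluded (`exclude_participants()`).
3. **Estimates slopes** (`estimate_slopes()`): per digit,
   dRT = mean right-hand RT − mean left-hand RT; per participant, OLS of
   dRT on digit magnitude (+ a −0.5/+0.5 parity contrast in PJ, giving the
   MARC slope), a categorical −0.5/+0.5 small/large model for MC, and
   Fisher-z standardized weights `atanh(r)`. A steeper negative magnitude
   slope is a stronger SNARC effect.
4. **Runs group inference** (`one_sample_t()`, `welch_t()`, `paired_t()`,
   `pearson_cor()`, `jonckheere_terpstra()`, `holm_correction()`): each
   t-test carries a JZS Bayes factor (Cauchy prior on effect size, r-scale
   0.707, numerical integration; `jzs_bf()`), correlations carry a default
   stretched-beta Bayes factor (`cor_bf()`); cross-cultural ordering is
   tested with a one-sided permutation Jonckheere–Terpstra trend test
   (2000 permutations).
5. **Classifies individual effects** (`h0_bootstrap()`): per participant,
   5000 null slopes are built by resampling two sets of 20 RTs per digit
   (ignoring hand) and refitting the slope model; an empirical slope below
   the 5th / above the 95th percentile is a reliable / reliable-reverse
   effect; prevalence tables are compared across groups with chi-square
   (`chi_square_independence()`) or Fisher's exact test
   (`fisher_exact_rxc()`).
6. **Scores the CDPQ** (`score_cdpq()`): LR = −1, RL = +1, none/mixed = 0;
   the −7..+7 sum score is trend-tested across groups and correlated with
   individual SNARC slopes.

## Worked example

Three simulated samples (20 participants each, defaults calibrated to the
published three-country group summaries), reduced resampling sizes so the
whole run takes a few seconds:

```r
library(snarcpipe)
cfgs <- default_group_configs()
for (i in seq_along(cfgs)) cfgs[[i]]$n_participants <- 20L
cfg <- run_config(master_seed = 2026, groups = cfgs,
                  n_boot = 1000, n_perm = 1000, out_dir = "results")
res <- run_pipeline(cfg)
subset(res$group_tests, task == "PJ" & measure == "SNARC")
```

```
   group  n mean_slope sd_slope     t df  p_value  bf10
  german 20      -5.63     8.90 -2.83 19 0.010655  4.86
 turkish 20      -5.45     6.05 -4.03 19 0.000713 49.10
 iranian 20       2.82     6.89  1.83 19 0.083091  0.94
```

Each row is the two-sided one-sample t-test of that group's mean
unstandardized PJ SNARC slope (ms per digit) against zero with its JZS
Bayes factor — at these small simulated sizes the German and Turkish
groups show a clear negative (regular) SNARC effect, the Iranian group
does not. The ordered-trend and pairwise comparisons:

```
 task                 comparison     test statistic   df  p_value    bf10
   PJ german < turkish < iranian jt_trend  822.0000   NA 0.000999      NA
   PJ           german < turkish  welch_t   -0.0753 33.5 0.470227   0.326
   PJ          turkish < iranian  welch_t   -4.0350 37.4 0.000130 195.192
```

and the H0-bootstrap prevalence of individually reliable effects:

```
print(res$prevalences$PJ_SNARC)
          reliable reliable_reverse unreliable
  german         8                1         11
  turkish        6                0         14
  iranian        0                6         14
```

`run_pipeline()` also writes every table (filter audit, exclusions,
slopes, group tests, trend tests, prevalence, CDPQ analyses, and a
`summary.json`) to the output directory.

A command-line interface with subcommands `simulate`, `preprocess`,
`slopes`, `infer`, `bootstrap`, `cdpq`, `all` is available via
`pipeline_cli()`; a launcher script is installed at
`system.file("cli", "snarc_pipeline.R", package = "snarcpipe")`.

## Methods documentation

See `vignettes/snarc-methods.Rmd` for the model, the filtering and
resampling conventions, every tunable constant with its default and
rationale, what the synthetic generator does and does not emulate, and
known limitations.
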