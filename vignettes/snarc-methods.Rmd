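---
title: "Models and methods behind snarcpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snarcpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snarcpipe)
```

## The problem

The SNARC effect is the observation that, in binary keypress tasks on
single digits, small numbers are answered faster with the left hand and
large numbers with the right. It is quantified per participant as the
slope of a regression of dRT (mean right-hand RT minus mean left-hand RT,
per digit) on digit magnitude: a more negative slope is a stronger
left-to-right association. The MARC effect is the analogous association of
parity with side, quantified by a contrast-coded parity predictor.
`snarcpipe` implements the full analysis chain used to compare these
effects across cultural samples: trial filtering, slope estimation, group
inference with default-prior Bayes factors, bootstrap classification of
individual effects, and scoring of a directional-preferences
questionnaire — plus a synthetic generator so that every stage is testable
without access to raw experimental data.

## Generative model of the synthetic data

Each simulated participant performs the standard design: two tasks (parity
judgment, PJ; magnitude classification, MC), each 2 blocks x 8 digits
(1, 2, 3, 4, 6, 7, 8, 9) x 20 repetitions, with the response-to-key
mapping reversed between blocks. A trial RT is

RT = mu_p + beta_blk [block = 2] + (s/2) (a_p + b_p d + m_p c(d)) + eps,

where s is +1 for right-side and -1 for left-side responses, d the digit,
c(d) the -0.5/+0.5 parity contrast, and eps ex-Gaussian noise (a Gaussian
of SD `noise_sd_within` plus an exponential tail of mean `exgauss_tau`).
Splitting the side-dependent term symmetrically makes the expected dRT for
digit d exactly `a_p + b_p d + m_p c(d)`, so with noise, errors and lapses
switched off the estimation stage recovers the drawn parameters *exactly*
— this generative identity is asserted in the test suite and is the
backbone of the pipeline's correctness argument.

Choices and defaults, with rationale:

* **Ex-Gaussian noise.** The standard descriptive model for RT
  distributions. `exgauss_tau` defaults to `0.6 * noise_sd_within` so that
  a single knob scales the whole noise process and `noise_sd_within = 0`
  is fully deterministic. The default `noise_sd_within = 100` ms yields
  estimated-slope dispersions of the size seen in published group tables.
* **True slope distributions.** `default_group_configs()` sets the three
  groups' PJ slope means/SDs to the published group summaries (-6.03
  (6.68) at n = 130; -3.43 (8.63) at n = 112; -1.69 (6.72) at n = 75), MC
  linear slopes to the published continuous-model means, and MARC means to
  the published values. The reference study reports no generative RT
  parameters, so baseline RT (600 ms Gaussian component, 80 ms
  between-participant SD) is set to a plausible value for young adults in
  online binary classification.
* **Errors and lapses.** Trials are answered incorrectly with probability
  `error_rate` (default 0.045, matching the reported ~4–5% error rates);
  error trials land on the wrong side and are *flagged, not removed*, so
  the preprocessing stage does the removal. With probability `lapse_rate`
  (default 0.015, matching the reported ~1–1.7% window removals) the RT is
  replaced by a draw outside the 200–1500 ms window.
* **Seeds.** Every participant's seed is a 31-bit hash of the master seed
  and the participant id (`derive_seed()`), so single participants can be
  re-simulated without re-running the study and all derived seeds stay
  below 2^31.
* **Questionnaire.** CDPQ items are drawn independently from per-item
  (LR, none, RL) probability triples; the default group triples are
  calibrated so the expected sum scores fall near the published group
  means (-3.65, -2.96, 0.07).

What the generator does **not** emulate: sequential (trial-history)
effects, speed–accuracy trade-offs, learning of the response mapping
across blocks, task-order effects (an additive `block_effect` exists but
defaults to 0), and digit-specific error rates. A green test therefore
establishes that the *analysis chain* is correct and well calibrated for
data of this structure — not that real data satisfy the model.

## Trial filtering and participant exclusion

Filters run per participant and task, in a fixed order: (1) incorrect
trials; (2) RTs outside [200, 1500] ms (inclusive bounds; values exactly
at a bound are kept); (3) iterative mean ± 3 SD trimming, pooled over the
whole task, repeated until convergence. The published criterion "until
means and SDs no longer changed" is operationalized as *the retained trial
set is identical between consecutive passes* — equivalent, exact, and free
of tolerance choices. The SD is the conventional n−1 estimator. The loop
must terminate because the retained set strictly shrinks (a hard cap of
100 passes is kept as a belt-and-braces guard).

Participants are excluded when, in either task, the retained fraction
falls below 0.75 or any digit x side cell is empty. The retention
denominator is *all* experimental trials of the task (320 in a full
design), i.e. "valid" counts losses from all three stages combined; the
source protocol does not state the denominator explicitly, and this
reading matches its practice of reporting combined exclusions. The
low-retention rule is checked before the empty-cell rule, so when both
hold the recorded reason is `low_retention`.

## Slope estimation

dRT uses retained correct trials only. The PJ model regresses the 8
per-digit dRTs on magnitude (1–4, 6–9) and the parity contrast; because
the two predictors are exactly orthogonal in this digit set, the magnitude
coefficient is unaffected by the parity term (asserted to 1e-10). The MC
categorical model codes small/large as -0.5/+0.5, so its slope is exactly
dRT(large) − dRT(small); the MC continuous model (magnitude as a linear
predictor) makes MC slopes comparable with PJ slopes.

Standardized slopes are Fisher-z transforms of standardized regression
weights. In these orthogonal designs the standardized weight equals the
zero-order correlation of dRT with the predictor, which is how it is
computed; with non-orthogonal predictors the two would differ. Two
numerical conventions: the weight is clamped to ±(1 − 1e-12) before
`atanh` so perfectly linear profiles give a large finite z rather than
±Inf, and a zero-variance dRT profile gets weight 0 (no evidence of
association; its unstandardized slope is 0 in any case).

Standardized MC slopes are computed from the categorical model — the same
model whose unstandardized slope is being standardized. The alternative
(continuous-model standardization) is available via `fit_mc_models()`.

## Group inference

*t-tests.* One-sample, Welch and paired tests are computed from the usual
closed forms (and, for published-table reproduction, from `(mean, SD, n)`
summaries directly). Zero-variance degenerate inputs yield an infinite
statistic with a limiting p of 0.

*JZS Bayes factors.* BF10 places a Cauchy(0, 0.707) prior on the
standardized effect size against a point null. The two-sided value uses
the standard inverse-gamma mixture representation of the marginal
likelihood, integrated with `stats::integrate` at relative tolerance
1e-8; one-sided values truncate (and renormalize) the Cauchy to the
hypothesized direction and integrate the noncentral-t likelihood. The two
routes satisfy the exact identity (BF_less + BF_greater)/2 = BF_two-sided,
which the tests assert. Two-sample tests use effective n = n1 n2/(n1+n2)
with df = n1+n2−2. Agreement with published values is expected to ~3
significant figures, not bit-exactly, because the published inputs are
rounded.

*Correlation Bayes factors.* The prior on the population correlation is a
stretched beta on (-1, 1). The width defaults to 1/3 — the de-facto
default of the Bayesian software family whose printed values this
implementation reproduces (a width-1, i.e. uniform, prior gives clearly
different numbers, e.g. 0.11 instead of 0.21 at r = -0.02, n = 130). The
marginal likelihood is integrated over the prior using the even part of
the reduced likelihood of r (a Gauss hypergeometric series), which is
exact for symmetric priors.

*Jonckheere–Terpstra.* The statistic counts, over ordered group pairs,
cross-group value pairs in increasing order, ties weighted 1/2 (computed
via rank sums). Significance comes from label permutations with the
add-one estimator p = (1 + #extreme)/(B + 1), which is never exactly 0 —
the standard bias-safe convention. The two-sided p doubles the smaller
directional p (capped at 1). The permutation p converges to the exact
full-enumeration null, which the test suite verifies on every group-size
pattern with up to 8 observations.

*Holm.* Step-down adjustment with running-maximum monotonicity, capped at
1. Which tests form a family is left to the caller, since the source
protocol did not prespecify families.

## H0 bootstrap classification

For each participant and task, each of 5000 iterations resamples, per
digit, two sets of 20 RTs with replacement from that digit's retained RTs
*pooled over both hands*, labels one set left and the other right, forms
the dRT profile, and refits the task's slope model. Conventions:

* The sampling pool contains only retained correct trials — filtered
  trials are not resurrected.
* The set size stays 20 regardless of how many trials a digit actually
  retains (the full design has up to 40), matching the reference
  procedure.
* PJ fits one two-predictor model per iteration and reads off both the
  SNARC (magnitude) and MARC (parity) null slopes from the same
  resamples — cheaper than two bootstraps and consistent with fitting one
  model per iteration. MC uses the categorical model, matching the
  empirical slope being classified.
* Percentiles use linear interpolation (R quantile type 7). A slope
  exactly at a bound is `unreliable`, because the classification rule uses
  strict inequalities.
* Per-participant bootstrap seeds derive from the master seed and the
  participant id, so classifications are reproducible in any execution
  order.

Under a null generator the proportion classified outside the 90% interval
is 10% by construction; the acceptance suite verifies 10% ± 2% over 500
simulated null participants at the full 5000 iterations.

## Contingency analyses

The chi-square test of independence is the closed-form Pearson statistic
without continuity correction. Fisher's exact test for r x c tables
enumerates all tables with the observed margins while the candidate space
stays within 1e6 tables (summing the probabilities of all tables no more
probable than the observed one, with a 1e-7 relative tie tolerance), and
otherwise switches to Monte-Carlo sampling of margin-fixed tables
(`stats::r2dtable`, add-one estimator, fixed seed). The questionnaire item
analysis switches from chi-square to Fisher exactly when some expected
cell frequency is below 5 — a decision that depends only on expected
frequencies, never on p-values.

## CDPQ scoring

Item responses reduce to LR (-1), RL (+1), NONE (0; "mixed" for the two
ordering items, "no preference" for the rest); accepted zero-code tokens
are `NONE`, `NP`, `MIXED`, `NO_PREFERENCE`, case-insensitively. For the
two ordering items the admissible raw patterns are not fully specified in
the source material; the package expects the data source to pre-code any
non-monotone ordering as `MIXED`, and documents this as a convention. The
sum score is order-invariant and bounded in [-7, 7] by construction.
Group-level analyses delegate to the generic machinery: per-item 3 x 3
contingency tests with Bonferroni-adjusted pairwise post-hocs, a one-sided
trend test on sum scores, and per-group score–slope correlations.

## Known limitations

* Simulated RT noise is homoscedastic within participant; real RT
  variance grows with the mean and differs between tasks.
* The bootstrap's null calibration is exact only to the extent that
  resampling 20-item sets mirrors the empirical slope's sampling
  variability; with very unequal left/right trial counts after filtering
  the 90% interval can be mildly mis-calibrated.
* One-sided Bayes factors depend on the truncation convention; published
  post-hoc values whose sidedness is not stated can be matched under
  either mode (`alternative = "less"/"greater"` vs `"two.sided"`), and
  both are provided.
* Welch degrees of freedom recomputed from rounded summary statistics can
  differ from published values in the second decimal (e.g. 207.58 vs
  207.48); this is input rounding, not an implementation difference.
* The pipeline deliberately stops short of mixed-effects or trial-level
  SNARC models, drift-diffusion decompositions, and psychometric
  validation of the questionnaire.
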