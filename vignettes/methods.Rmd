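---
title: "Methods: personalised language networks and episode dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalised language networks and episode dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, its synthetic
world, the numerical choices behind the estimator, and the places where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The scientific question

Network accounts of depression hold that symptoms (or here, outwardly
observable language features associated with depression) interact and
reinforce one another, and that the *connectivity* of that interaction
network rises when a person is in, or near, a depressive episode. Testing
this within-subject requires long daily time series per person. The package
operationalises the full chain: daily word-category percentages from
cleaned documents, per-person sparse network estimation, connectivity
summaries, and between/within-subject inference with explicit controls for
the main confound (unequal numbers of observation days).

## 2. Text features

Documents are cleaned by removing URLs and @-mentions whole, stripping the
`#` symbol (the word is kept — a hashtagged word is an ordinary word with a
prefix symbol, while a mention is a handle; both choices are configurable),
deleting emojis and all other non-alphanumerics except `.`, `!`, `?`, which
are retained as separate tokens because sentence counting needs them.
Retained punctuation is excluded from the word count. All documents of one
user-day are concatenated before scoring (daily bins); days with no
documents simply do not exist in the series, and days outside the 365 days
before the survey are dropped.

Scoring uses a LIWC-style dictionary dialect (`%`-delimited header of
`id<TAB>name` categories, then `pattern<TAB>id...` entries, stems marked by
a trailing `*`). A category's daily value is `100 * matched / word_count`; a
token may count toward several categories; an exact-word entry shadows stem
entries for the same token, mirroring the usual dictionary-tool precedence
(a union policy is available). The shipped dictionary is a small synthetic
stand-in with the nine a-priori category *names* (pronoun classes, positive
and negative emotion, swearing, articles, negations); the real commercial
lexicon is proprietary and is not reproduced.

## 3. Episode recoding

Self-reported episode intervals (up to five per person) are recoded:
overlapping or touching reports are unioned; intervals separated by 13 or
fewer intervening days are merged, the gap becoming depressed time; then
any residual interval shorter than 14 days (inclusive day counting,
`end - start + 1`) is recoded to "not depressed". Merging happens *before*
dropping, so two sub-threshold reports that jointly describe one >= 2-week
episode survive; the reverse order is available (`order = "drop_first"`).
The source description fixes neither the order nor inclusive counting;
both choices are flagged here rather than claimed as the original's.
Eligibility: 30 observed days for the between-subject analyses, 15 observed
days both within and outside an episode for the paired analyses. Both
bounds are inclusive.

## 4. The GVAR estimator

For standardised (person-level z-scored) series, lag pairs are built under
the `concatenate` policy — consecutive *observed* rows are paired even
across calendar gaps, mirroring the upstream handling of missing days; a
`calendar` policy restricted to truly adjacent days is available, since the
statistically safer choice is ambiguous.

One fit minimises the penalised negative Gaussian log-likelihood by
alternating:

1. **B-step** — coordinate descent on all `p^2` entries of the temporal
   matrix under the precision-weighted loss
   `tr(K (Y - XB')'(Y - XB'))/(2n) + lambda_B ||B||_1` (an MRCE-type
   update); rank-one updates of the working gradient keep a sweep at
   `O(p^4)` independent of series length, because the whole problem is
   expressed through `X'X/n`, `X'Y/n`, `Y'Y/n`.
2. **K-step** — graphical lasso (block coordinate descent, off-diagonal
   penalty only, diagonal of the working covariance fixed at the residual
   variances) on the residual covariance.

Alternation stops when the max-abs parameter change falls below `1e-4`
(100 iterations cap, convergence flagged). Entries whose magnitude is
indistinguishable from the soft-threshold boundary (`< 1e-10` relative) are
snapped to exact zero so edge counts are well defined.

**Grids.** Both penalties get `n_lambda = 10` log-spaced values down to
`0.01` of their maximum. The `lambda_kappa` maximum is the largest absolute
off-diagonal of the lag-0 covariance; the `lambda_beta` maximum is
`max_ij |(X'Y/n)_ij| / s_jj`, the exact stationarity threshold at which B
vanishes given the fully shrunk diagonal K — the per-response rescaling
(a factor `n/(n-1)` on standardised data) makes "the grid maximum yields
the empty network" a provable property rather than an approximation.

**Selection.** EBIC with `gamma = 0` (i.e. BIC), counting as parameters the
nonzero entries of B plus the nonzero upper-triangle off-diagonals of K;
ties break toward the smaller penalty pair, consistent with the
dense-preferring intent of `gamma = 0`. An optional post-selection step
(`fit_config(refit = TRUE)`) re-estimates B and K unpenalised on the
selected support, mirroring the reference tooling's refit convention;
unshrunk weights are noticeably inflated on short series (see §8).

**Degenerate inputs.** A zero-variance node is an error naming the node —
silent dropping would change the network size mid-pipeline. A non-PD
residual covariance in the unpenalised limit receives a logged ridge
jitter.

## 5. Connectivity, centrality, stability

Node strength is the sum of absolute contemporaneous partial correlations
at a node; global strength is their mean (this convention, not the sum).
Group summaries apply a single-pass 3-SD exclusion per node before
averaging; mean networks average element-wise over unmasked users.
Closeness and betweenness are computed only on mean networks (individual
networks are too sparse for them to be stable), on the weighted graph with
edge distance `1/|omega|`.

Case-dropping stability treats *days* as the sampling unit of a
personalised fit: for each drop proportion (grid up to 0.75), random row
subsets are refit and their node strengths correlated (Pearson — the
reference tooling's default; contiguous-block dropping is not implemented
because the upstream procedure is unstated) with the full-sample strengths.
The CS coefficient is the largest proportion whose 5th-percentile
correlation stays at or above 0.7; values of 0.5 or more are conventionally
interpretable. If the full-sample network is empty there is nothing to
correlate and CS is defined as 0 (previously an empty subsample "agreed
perfectly" with an empty full sample, which is meaningless).

## 6. Inference

*Between subject*: severity scores from different questionnaires are each
z-scored by their own scale's mean/SD and pooled. Feature–severity
associations are uncorrected two-sided Pearson tests plus standardised
simple-regression slopes (whether the originals were simple or partial
models is unstated; simple was chosen and flagged). Severity–strength
models are OLS with optional day-count covariate. Split-half edge
reliability uses a seeded random half-split and correlates the two mean
networks over the 36 unique edges, optionally excluding the strongest edge.

*Within subject*: two networks per eligible person (within/outside days;
lag pairs never straddle the boundary). The episode effect is a linear
model on the stacked two-rows-per-user table with fixed per-user
intercepts — with no covariates the episode coefficient *is* the mean
paired difference (an exact identity the tests assert); a random-intercept
variant was considered and rejected as needless machinery for exactly
paired data. Covariate options: day count, and day count plus its
interaction with the episode indicator. The 80% bootstrap subsamples users
*without* replacement ("a bootstrapped sample of 80%" is ambiguous;
subsampling was chosen and flagged). The permutation null relabels, per
user, a uniformly random day subset of size `n_days_within` as fake-within
— preserving each user's day counts exactly — and *re-estimates* both
networks per draw; re-estimation is the default because a label swap on
precomputed networks cannot generate any day-count bias at all, and the
contiguous-block alternative is left unimplemented since the plain reading
of label shuffling is subset randomisation. Empirical p is
`(1 + #{null >= observed}) / (n_perm + 1)`.

*Generalisation*: features are split into severity-relevant and irrelevant
pools at uncorrected p < 0.05; random k-feature sets (duplicates across
draws allowed) are pushed through the full day-count-adjusted episode
pipeline; per-set episode coefficients are compared across pools by OLS on
a pool indicator, and top sets are ranked by coefficient (not significance
— the original's ranking is unstated) with inclusion frequencies reported.

## 7. The synthetic world

The generator *is* the estimator's model class: a stationary lag-1 GVAR
whose innovation precision switches between `K_out` and a within-episode
version with all off-diagonals multiplied by `c` (so every partial
correlation scales by `c`; positive-definiteness is checked at
construction). Defaults, chosen once:

- `n_days = 365`, `p = 9`; episode count Poisson with mean 1.56 capped at
  five reports, log-normal durations with mean 104 and SD 97 days
  (positive, right-skewed), schedules recoded by the same rules as real
  data;
- `K_out` has one strong partial correlation (0.40) and four weak ones
  (0.10–0.12): daily language networks are sparse with one dominant edge
  and mostly near-zero weights, and individual fitted networks should be
  sparse;
- missingness i.i.d. Bernoulli(0.2) — the simplest mechanism consistent
  with "days without documents do not exist"; posting-time structure and
  burstiness are out of scope;
- latent-to-percentage map `100 * plogis((y - center)/scale)` — keeps
  percentages in (0, 100) without truncation artefacts; since fits
  standardise per person, the monotone map is nearly harmless;
- severity = (weight × cohort-standardised true mean connectivity) +
  feature-mean slopes + Gaussian noise (SD 0.5), then z-scored; the
  standardisation makes the weight interpretable in cohort-SD units. Users
  also receive latent mean shifts (SD 0.3) so feature means vary between
  people. Severity is emitted on two synthetic questionnaire scales to
  exercise the scale-combination step;
- the optional document renderer draws tokens i.i.d. from a per-day
  category mixture (scaled-logistic probabilities, remainder to
  out-of-dictionary filler), so the text module can be validated against
  known generating probabilities.

What a green test does **not** establish: robustness to heavy-tailed,
zero-inflated feature distributions (real word-category percentages are
both; the generator is Gaussian under a monotone map), to non-random
missingness, to recall error in episode dates, or to any deviation from the
lag-1 Markov structure.

## 8. The day-count bias, and one deliberately red criterion

Networks fitted on few days look different from networks fitted on many.
In this estimator, on the synthetic world, mean estimated global strength
as a function of series length has two regimes (the test suite measures
both): below roughly 20 observed days, fits are near-singular (barely more
lag pairs than nodes) and BIC at `gamma = 0` happily selects explosive
dense models — mean strength at 17 days is ~30× the value at 170 days,
reproducing the reported "largest connectivity during short (under 30-day)
periods". Above ~30 days the curve *rises* slowly with length, because
weak true edges cross the BIC detection threshold as evidence accumulates.

Consequently the naive unadjusted within/outside contrast is not calibrated
when within periods are systematically shorter — which is exactly the
confound the upstream analysis identified. The package's corrected
pipeline (3-SD strength mask + day-count covariate) is calibrated on null
cohorts and powerful on multiplier-1.5 cohorts, and the acceptance suite
asserts both.

One acceptance criterion expects the *permutation null mean* to be positive
(short fake-within networks looking denser) on a null cohort mirroring the
studied day-count asymmetry (~80 within vs ~170 outside observed days,
within-SD ~60). On the Gaussian synthetic world the measured null mean is
slightly **negative**: at that composition too few users sit in the sub-20-day
inflation zone, and the rising detection curve dominates. The upstream
positive bias at the same composition plausibly rides on heavy-tailed real
data inflating small-sample covariances — a feature this generator
deliberately lacks (§7). The criterion is implemented exactly as stated and
left red rather than quietly reshaping the cohort toward shorter episodes;
the accompanying assertions (matched day-count composition; the sub-20-day
inflation mechanism itself) pass.

## 9. Numerical notes

- All solver work happens on sufficient statistics; a full 10 × 10 grid fit
  for p = 9 and a year of days takes ~0.1 s, so permutation and stability
  experiments run at full fidelity in the test suite.
- Warm starts follow the grid path (outer loop over `lambda_beta`
  descending, inner over `lambda_kappa`).
- Fits contain no randomness: identical inputs give bit-identical outputs.
  Every stochastic procedure (generator, bootstraps, permutations,
  half-splits, feature-set draws) takes an explicit integer seed.
- Reduced desk-scale defaults are used in tests where the criteria allow
  ("reduced grid settings": `n_lambda = 4`; `n_perm = n_boot = 200`); the
  full-scale settings sit behind ordinary arguments, e.g. the CLI's
  `--full` for the 1000+1000-set generalisation run.

## 10. Known limitations

Higher-order lags, time-varying coefficients, and nonparanormal transforms
for non-Gaussian nodes are out of scope. Closeness/betweenness are not
computed for individual networks. The dictionary is a toy; real lexicon
effects (category overlap at scale, stem collisions) are only lightly
exercised. The permutation test re-estimates ~2 × n_users networks per
draw and is the one genuinely expensive operation at full scale.
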