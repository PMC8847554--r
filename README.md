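# lingnet

Personalised network dynamics of daily language features.

`lingnet` is an R package for asking whether the *connectivity* of a
person's network of depression-related language features changes with their
mental-health state. It targets study designs where each participant
contributes roughly a year of short timestamped documents (e.g. social-media
posts), a word-category dictionary turns each day's text into
feature percentages, participants self-report the dates of any depressive
episodes, and a questionnaire provides current depression severity. Because
raw data of this kind is typically protected, the package ships a
synthetic-cohort generator with known ground truth so the entire pipeline is
testable end to end.

## The model

For each person, the daily feature vector `y_t` (p = 9 a-priori features by
default) follows a lag-1 graphical vector autoregression (GVAR):

```
y_t = B y_{t-1} + e_t,     e_t ~ N(0, K^{-1})
```

`B` captures day-to-day (temporal) effects; the innovation precision `K`
encodes same-day conditional dependencies, reported as contemporaneous
partial correlations

```
omega_ij = -kappa_ij / sqrt(kappa_ii * kappa_jj).
```

Estimation alternates an L1-penalised update of `B` (coordinate descent on
the precision-weighted Gaussian loss) with a graphical-lasso update of `K`
on the residual covariance, over a 10 x 10 penalty grid, selecting by EBIC
with gamma = 0 (i.e. the BIC, which prefers denser networks). Connectivity
is summarised by **node strength** `s_i = sum_j |omega_ij|` and **global
strength** (the mean of node strengths). Downstream inference includes:

- between-subject regressions of strength on depression severity,
- the within-subject contrast of networks estimated *within* vs *outside*
  recoded episode intervals (>= 2-week episodes, <2-week gaps merged),
  with day-count covariates, an 80% subsample bootstrap, a Wilcoxon
  signed-rank check, and a day-label permutation null that preserves each
  person's within/outside day counts,
- case-dropping stability (CS coefficient: the largest fraction of days
  that can be dropped while the 5th-percentile correlation with the
  full-sample strengths stays >= 0.7),
- a generalisation experiment over random 9-feature sets drawn from
  severity-relevant vs irrelevant feature pools.

## Worked example

```r
library(lingnet)

# a synthetic cohort: 40 users, 1 year of daily 9-feature percentages,
# episodes whose innovation precision off-diagonals are scaled by 1.5
cfg    <- generator_config(n_users = 40, connectivity_multiplier = 1.5,
                           seed = 2024)
cohort <- suppressMessages(simulate_cohort(cfg))

# one personalised network
fit <- estimate_network(cohort$users[[1]]$features, config = fit_config())
fit
#> Personalised GVAR fit: 9 nodes, 292 lag pairs
#>   lambda_beta = 0.166, lambda_kappa = 0.07913, EBIC = 2487.94
#>   contemporaneous edges: 6 nonzero of 36
round(node_strength(fit), 3)
#>    f1    f2    f3    f4    f5    f6    f7    f8    f9
#> 0.528 0.619 0.098 0.098 0.048 0.088 0.000 0.000 0.060

# within vs outside episode contrast (15/15-day eligibility, 3-SD strength
# mask, day-count covariate)
pa  <- suppressMessages(cohort_paired_analysis(cohort,
                                               config = fit_config(n_lambda = 4)))
eff <- episode_effect(mask_paired_strengths(pa$table), covariates = "n_days")
eff
#>      term      beta         se      p_value                                   model  n
#> 1 episode 0.1752016 0.03440918 2.158289e-05 within-subject ols, covariates = n_days 30
```

The episode coefficient is the adjusted mean increase in global network
strength when the same people are inside a depressive episode — here
+0.175 strength units, strongly positive because the generator raised
within-episode partial correlations by 50%. A paired signed-rank test
agrees (`wilcoxon_paired(...)`: V = 325, p = 0.00113 on this cohort).

Nodes f1–f2 dominate strength because the generator's default truth has one
strong edge (|omega| = 0.40) between them plus a handful of weak edges —
mimicking the sparse, weak-edged networks typical of daily language data.

## Command line

```sh
Rscript inst/cli/lingnet.R simulate --users 20 --seed 1 --render --out cohort/
Rscript inst/cli/lingnet.R features --docs cohort/documents.jsonl \
    --dict inst/extdata/toy_dictionary.dic --survey-date 2020-12-31 --out features.csv
Rscript inst/cli/lingnet.R episodes --in cohort/episodes.csv \
    --features features.csv --survey-date 2020-12-31 --out labels.csv
Rscript inst/cli/lingnet.R fit --features features.csv --survey-date 2020-12-31 --out networks/
```

Further subcommands: `centrality`, `stability`, `episode-effect`, `permute`,
`bootstrap`, `generalize` (see `inst/cli/lingnet.R`).

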