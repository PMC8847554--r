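# two-row-per-user table builder for identity tests
toy_table <- function(within, outside, n_w = 50, n_o = 150) {
  n <- length(within)
  data.frame(user_id = rep(paste0("u", seq_len(n)), each = 2),
             period = rep(c("within", "outside"), n),
             episode = rep(c(1L, 0L), n),
             global_strength = as.vector(rbind(within, outside)),
             n_days = rep(c(n_w, n_o), n))
}

test_that("episode beta equals the mean paired difference exactly", {
  set.seed(1)
  w <- runif(20, 0.2, 0.8)
  o <- runif(20, 0.2, 0.8)
  eff <- suppressWarnings(episode_effect(toy_table(w, o)))
  expect_equal(eff$beta, mean(w - o), tolerance = 1e-12)
  # trivial identities
  expect_equal(suppressWarnings(episode_effect(toy_table(o, o)))$beta, 0,
               tolerance = 1e-12)
  eff01 <- suppressWarnings(episode_effect(toy_table(o + 0.1, o)))
  expect_equal(eff01$beta, 0.1, tolerance = 1e-12)
  expect_lt(eff01$p_value, 1e-10)
})

test_that("day-count covariates and interaction terms are accepted", {
  set.seed(2)
  w <- runif(30); o <- runif(30)
  tab <- toy_table(w, o)
  tab$n_days <- tab$n_days + rpois(60, 20)
  for (cv in c("n_days", "n_days_plus_interaction")) {
    eff <- episode_effect(tab, covariates = cv)
    expect_true(is.finite(eff$beta) && is.finite(eff$p_value))
  }
  expect_error(episode_effect(toy_table(w[1], o[1])), "at least 2 users")
})

test_that("wilcoxon_paired matches a hand enumeration on 5 pairs", {
  w <- c(1.2, 0.8, 1.5, 0.9, 1.1)
  o <- c(1.0, 1.0, 1.0, 1.0, 1.0)
  got <- wilcoxon_paired(w, o)
  # signed ranks of d = (0.2, -0.2, 0.5, -0.1, 0.1): |d| ranks with ties
  d <- w - o
  rk <- rank(abs(d))
  V_hand <- sum(rk[d > 0])
  expect_equal(got$V, V_hand)
  mirrored <- wilcoxon_paired(o, w)
  expect_equal(mirrored$p_value, got$p_value)
  expect_warning(res0 <- wilcoxon_paired(o, o), "zero")
  expect_equal(res0$p_value, 1)
})

test_that("bootstrap_effect is reproducible and honours identities", {
  set.seed(3)
  o <- runif(12, 0.2, 0.6)
  tab <- toy_table(o + 0.1, o)
  bt <- suppressWarnings(bootstrap_effect(tab, n_boot = 50, seed = 7))
  expect_true(all(abs(bt$betas - 0.1) < 1e-12))
  bt2 <- suppressWarnings(bootstrap_effect(tab, n_boot = 50, seed = 7))
  expect_identical(bt$betas, bt2$betas)
  expect_error(bootstrap_effect(toy_table(o[1:3], o[1:3])), "at least 5")
})

test_that("bootstrap distribution is centred near zero on null tables", {
  set.seed(4)
  o <- runif(40, 0.2, 0.6)
  w <- o + rnorm(40, 0, 0.05)           # no systematic difference
  bt <- bootstrap_effect(toy_table(w, o), n_boot = 200, seed = 5)
  expect_lt(abs(bt$mean), 2 * sd(w - o) / sqrt(40) + 2 * bt$se)
})

test_that("fit_paired_networks enforces eligibility and splits day sets", {
  y <- simulate_gvar_series(default_temporal(4), default_precision(4), 80,
                            seed = 6)
  labs <- rep(c("within", "outside"), each = 40)
  pn <- fit_paired_networks(y, labs, config = quick_cfg())
  expect_s3_class(pn, "paired_networks")
  expect_equal(pn$n_days_within, 40)
  expect_equal(pn$within_fit$n_days, 40)
  expect_identical(pn$within_fit$node_names, pn$outside_fit$node_names)
  # all days within -> no outside network
  expect_message(
    pn0 <- fit_paired_networks(y, rep("within", 80), config = quick_cfg()),
    "ineligible")
  expect_null(pn0)
  # 14 within days is one short of eligibility
  labs14 <- c(rep("within", 14), rep("outside", 66))
  expect_message(
    expect_null(fit_paired_networks(y, labs14, config = quick_cfg())),
    "ineligible")
})

test_that("paired strength table has the documented shape", {
  y <- simulate_gvar_series(default_temporal(4), default_precision(4), 100,
                            seed = 8)
  labs <- rep(c("within", "outside"), 50)
  pn <- fit_paired_networks(y, labs, config = quick_cfg())
  pn$user_id <- "u1"
  tab <- paired_strength_table(list(pn))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$episode, c(1L, 0L))
  expect_equal(tab$global_strength[1], global_strength(pn$within_fit))
  expect_true(all(paste0("V", 1:4) %in% names(tab)))
})

test_that("permutation preserves day counts and its p-value is well-formed", {
  set.seed(9)
  mats <- lapply(1:4, function(i)
    simulate_gvar_series(default_temporal(4), default_precision(4), 60,
                         seed = 20 + i))
  names(mats) <- paste0("u", 1:4)
  labs <- lapply(1:4, function(i)
    sample(rep(c("within", "outside"), c(25, 35))))
  names(labs) <- names(mats)
  pr <- permutation_null(mats, labs, config = quick_cfg(), n_perm = 19,
                         seed = 30)
  expect_length(pr$null_betas, 19)
  expect_gte(pr$empirical_p, 1 / 20)
  expect_lte(pr$empirical_p, 1)
  expect_equal(pr$empirical_p,
               (1 + sum(pr$null_betas >= pr$observed_beta)) / 20)
  pr2 <- permutation_null(mats, labs, config = quick_cfg(), n_perm = 19,
                          seed = 30)
  expect_identical(pr$null_betas, pr2$null_betas)
})

test_that("permutation p-values are not concentrated low under a null", {
  # small null cohorts with equal within/outside day counts; exchangeable
  # labels make the permutation p exactly valid, so rejections at 0.05 are
  # Binomial(12, ~0.05): 3+ of 12 has probability ~2%
  ps <- vapply(1:12, function(r) {
    mats <- lapply(1:5, function(i)
      simulate_gvar_series(default_temporal(4), default_precision(4), 70,
                           seed = 100 * r + i))
    names(mats) <- paste0("u", 1:5)
    set.seed(500 + r)
    labs <- lapply(1:5, function(i)
      sample(rep(c("within", "outside"), c(35, 35))))
    names(labs) <- names(mats)
    permutation_null(mats, labs, config = quick_cfg(), n_perm = 39,
                     seed = 40 + r)$empirical_p
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 2)
  expect_gt(mean(ps), 0.25)          # roughly uniform, not collapsed at 0
})

test_that("cohort_paired_analysis wires the cohort through", {
  cfg <- generator_config(8, n_days = 200, connectivity_multiplier = 1.5,
                          episode_rate = 2, seed = 12)
  co <- suppressMessages(simulate_cohort(cfg))
  pa <- suppressMessages(cohort_paired_analysis(co, config = quick_cfg()))
  expect_true(length(pa$paired) >= 1)
  expect_equal(nrow(pa$table), 2 * length(pa$paired))
  expect_setequal(names(pa$matrices), names(pa$labels))
})
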