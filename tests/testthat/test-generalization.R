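test_that("sample_feature_sets draws uniform distinct subsets", {
  pool <- paste0("f", 1:9)
  sets <- sample_feature_sets(pool, k = 9, n_sets = 5, seed = 1)
  for (s in sets) expect_setequal(s, pool)
  expect_error(sample_feature_sets(pool[1:5], k = 9, n_sets = 2), "at least 9")
  a <- sample_feature_sets(paste0("f", 1:20), k = 4, n_sets = 10, seed = 3)
  b <- sample_feature_sets(paste0("f", 1:20), k = 4, n_sets = 10, seed = 3)
  expect_identical(a, b)
  # inclusion frequency ~ k / |pool|
  big <- sample_feature_sets(paste0("f", 1:20), k = 4, n_sets = 2000, seed = 5)
  freq <- table(unlist(big)) / 2000
  expect_true(all(abs(freq - 4 / 20) < 0.03))
  expect_true(all(vapply(big, function(s) length(unique(s)), integer(1)) == 4))
})

make_small_cohort <- function(mult = 1.5, n_users = 10, seed = 31) {
  cfg <- generator_config(n_users, n_days = 180, n_features = 6,
                          temporal_matrix = default_temporal(6),
                          precision_outside = default_precision(6),
                          connectivity_multiplier = mult,
                          episode_rate = 2, episode_duration_mean_days = 60,
                          episode_duration_sd_days = 30,
                          missing_day_prob = 0.1, seed = seed)
  suppressMessages(simulate_cohort(cfg))
}

test_that("the a priori set reproduces the direct episode analysis bit-for-bit", {
  co <- make_small_cohort()
  direct <- suppressMessages(cohort_paired_analysis(co, config = quick_cfg()))
  eff_direct <- episode_effect(direct$table, covariates = "n_days")
  res <- suppressMessages(
    episode_effect_per_set(list(paste0("f", 1:6)), co, config = quick_cfg(),
                           pool_label = "relevant"))
  expect_equal(res$beta, eff_direct$beta, tolerance = 1e-12)
  expect_equal(res$se, eff_direct$se, tolerance = 1e-12)
  expect_equal(res$n_users, eff_direct$n)
})

test_that("compare_pools recovers exact shifts and rejects single pools", {
  base <- data.frame(set_id = 1:40, pool = rep(c("irrelevant", "relevant"), 20),
                     features = "x", beta = rnorm(40, 0, 0.01),
                     se = 0.01, p_value = 0.5, n_users = 10)
  base$beta[base$pool == "relevant"] <-
    base$beta[base$pool == "irrelevant"] + 0.01
  eff <- suppressWarnings(compare_pools(base))
  expect_equal(eff$beta, 0.01, tolerance = 1e-12)
  expect_error(compare_pools(base[base$pool == "relevant", ]), "both pools")
  # identical distributions: no pool effect
  same <- base; same$beta <- rep(rnorm(20, 0, 0.01), each = 2)
  expect_gt(compare_pools(same)$p_value, 0.05)
})

test_that("top_network_report counts inclusion frequencies correctly", {
  res <- data.frame(set_id = 1:6, pool = "relevant",
                    features = c("a|b", "a|c", "a|b", "b|c", "a|d", "c|d"),
                    beta = c(6, 5, 4, 3, 2, 1), se = 1, p_value = 0.5,
                    n_users = 5)
  rep3 <- top_network_report(res, top_n = 3)
  expect_equal(rep3$top_sets$set_id, 1:3)
  freq <- setNames(rep3$frequency$count, rep3$frequency$feature)
  expect_equal(freq[["a"]], 3L)
  expect_equal(freq[["b"]], 2L)
  expect_equal(sum(rep3$frequency$count), 3 * 2)   # top_n * k identity
  expect_error(top_network_report(res, top_n = 10), "only 6")
  # all sets identical -> every member at 100%
  allsame <- res; allsame$features <- "a|b"
  expect_true(all(top_network_report(allsame, 6)$frequency$proportion == 1))
})

test_that("planted connectivity signal separates the pools", {
  # features 1-3 carry the within-episode connectivity increase, 4-6 do not
  K <- diag(1, 6)
  K[1, 2] <- K[2, 1] <- -0.35
  K[2, 3] <- K[3, 2] <- -0.3
  K[4, 5] <- K[5, 4] <- -0.3        # static edge among irrelevant features
  Kin <- K
  Kin[1, 2] <- Kin[2, 1] <- -0.35 * 1.8
  Kin[2, 3] <- Kin[3, 2] <- -0.3 * 1.8
  cfg <- generator_config(12, n_days = 200, n_features = 6,
                          temporal_matrix = matrix(0, 6, 6),
                          precision_outside = K, connectivity_multiplier = 1,
                          episode_rate = 2, episode_duration_mean_days = 70,
                          episode_duration_sd_days = 30,
                          missing_day_prob = 0, seed = 77)
  co <- suppressMessages(simulate_cohort(cfg))
  # re-generate the within-episode days under the boosted precision
  L_in <- t(chol(solve(Kin)))
  for (i in seq_along(co$users)) {
    u <- co$users[[i]]
    w <- label_days(u$episodes, u$features) == "within"
    if (!any(w)) next
    set.seed(1000 + i)
    boosted <- t(L_in %*% matrix(rnorm(6 * sum(w)), 6))
    vals <- u$features$values
    vals[w, ] <- 100 * plogis(boosted)
    co$users[[i]]$features$values <- vals
  }
  rel_sets <- sample_feature_sets(paste0("f", 1:3), k = 3, n_sets = 6,
                                  seed = 2)
  irr_sets <- sample_feature_sets(paste0("f", 4:6), k = 3, n_sets = 6,
                                  seed = 3)
  rel <- suppressMessages(episode_effect_per_set(
    rel_sets, co, config = quick_cfg(), pool_label = "relevant"))
  irr <- suppressMessages(episode_effect_per_set(
    irr_sets, co, config = quick_cfg(), pool_label = "irrelevant"))
  expect_gt(mean(rel$beta), mean(irr$beta))
  eff <- compare_pools(rbind(rel, irr))
  expect_gt(eff$beta, 0)
})
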