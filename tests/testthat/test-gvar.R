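test_that("make_lag_pairs implements both pairing policies", {
  x <- matrix(rnorm(30 * 3), 30, 3)
  pr <- make_lag_pairs(x)
  expect_equal(nrow(pr$current), 29)
  expect_equal(pr$current[1, ], x[2, ])
  expect_equal(pr$lagged[29, ], x[29, ])

  x4 <- matrix(rnorm(4 * 2), 4, 2)
  days <- as.Date("2021-01-01") + c(0, 1, 4, 5)
  expect_equal(nrow(make_lag_pairs(x4, "concatenate", days)$current), 3)
  cal <- make_lag_pairs(x4, "calendar", days)
  expect_equal(nrow(cal$current), 2)
  expect_equal(cal$lagged, x4[c(1, 3), ])

  expect_error(make_lag_pairs(x[1, , drop = FALSE]), "insufficient data")
})

test_that("standardise_series z-scores with full-series statistics", {
  x <- matrix(rnorm(50 * 3, mean = 5, sd = 2), 50, 3)
  x <- scale(x)[, ]                      # z-scored full series
  pr <- make_lag_pairs(x)
  st <- standardise_series(pr$current, pr$lagged)
  expect_lt(max(abs(st$current - pr$current)), 1e-12)
  expect_lt(max(abs(st$lagged - pr$lagged)), 1e-12)

  y <- matrix(rnorm(40 * 2, 10, 3), 40, 2)
  pry <- make_lag_pairs(y)
  sty <- standardise_series(pry$current, pry$lagged)
  full <- rbind(sty$lagged, sty$current[nrow(sty$current), , drop = FALSE])
  expect_equal(unname(colMeans(full)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(full, 2, sd)), c(1, 1), tolerance = 1e-12)

  y[, 2] <- 7
  colnames(y) <- c("ok", "flat")
  pry <- make_lag_pairs(y)
  expect_error(standardise_series(pry$current, pry$lagged),
               "zero-variance node.*flat")
})

test_that("lambda_grid has the documented shape", {
  set.seed(2)
  x <- matrix(rnorm(100 * 4), 100, 4)
  pr <- make_lag_pairs(x)
  st <- standardise_series(pr$current, pr$lagged)
  g <- lambda_grid(st$current, st$lagged, fit_config())
  expect_length(g$beta, 10)
  expect_length(g$kappa, 10)
  expect_true(all(diff(g$beta) < 0))
  expect_true(all(diff(g$kappa) < 0))
  n <- nrow(st$current)
  syy <- crossprod(st$current) / n
  expect_equal(g$kappa[1], max(abs(syy[upper.tri(syy)])))
  sxy <- crossprod(st$lagged, st$current) / n
  expect_equal(g$beta[1], max(sweep(abs(sxy), 2, diag(syy), "/")))
  expect_equal(g$beta[10], g$beta[1] * 0.01, tolerance = 1e-10)

  g1 <- lambda_grid(st$current, st$lagged, fit_config(n_lambda = 1))
  expect_length(g1$kappa, 1)
  expect_equal(g1$kappa, g$kappa[1])
})

test_that("full shrinkage yields the empty network", {
  set.seed(3)
  x <- matrix(rnorm(120 * 5), 120, 5)
  pr <- make_lag_pairs(x)
  st <- standardise_series(pr$current, pr$lagged)
  g <- lambda_grid(st$current, st$lagged, fit_config())
  f <- fit_at(st$current, st$lagged, 2 * g$beta[1], 2 * g$kappa[1])
  expect_true(all(f$B == 0))
  expect_true(all(f$K[upper.tri(f$K)] == 0))
  # the largest kappa grid value itself already gives an empty K
  f2 <- fit_at(st$current, st$lagged, g$beta[1], g$kappa[1])
  expect_true(all(f2$K[upper.tri(f2$K)] == 0))
})

test_that("unpenalised fit matches the OLS matrix-inversion oracle", {
  y <- simulate_gvar_series(default_temporal(4), default_precision(4), 1500,
                            seed = 5)
  pr <- make_lag_pairs(y)
  st <- standardise_series(pr$current, pr$lagged)
  f <- fit_at(st$current, st$lagged, 0, 0)
  X <- st$lagged; Y <- st$current
  B_ols <- t(solve(crossprod(X), crossprod(X, Y)))
  K_ols <- solve(crossprod(Y - X %*% t(B_ols)) / nrow(Y))
  expect_lt(max(abs(f$B - B_ols)), 1e-5)
  expect_lt(max(abs(f$K - K_ols)), 1e-5)
})

test_that("independent columns yield a near-empty selected network", {
  set.seed(6)
  y <- matrix(rnorm(400 * 5), 400, 5)
  fit <- estimate_network(y, config = fit_config())
  expect_lt(max(abs(fit$omega)), 0.05)
})

test_that("pcc_from_precision matches closed forms and the conditioning oracle", {
  expect_true(all(pcc_from_precision(diag(4)) == 0))
  K2 <- matrix(c(1, -0.3, -0.3, 1), 2)
  expect_equal(pcc_from_precision(K2)[1, 2], 0.3)
  expect_error(pcc_from_precision(matrix(c(1, 0.2, 0.3, 1), 2)), "symmetric")
  expect_error(pcc_from_precision(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  set.seed(8)
  for (rep in 1:5) {
    A <- matrix(rnorm(25), 5)
    K <- crossprod(A) + diag(5)
    expect_equal(pcc_from_precision(K), conditioning_pcc(K),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("select_ebic reduces to an independent BIC at gamma 0", {
  y <- simulate_gvar_series(default_temporal(4), default_precision(4), 200,
                            seed = 9)
  pr <- make_lag_pairs(y)
  st <- standardise_series(pr$current, pr$lagged)
  g <- lambda_grid(st$current, st$lagged, quick_cfg())
  fits <- list()
  for (lb in g$beta) for (lk in g$kappa)
    fits[[length(fits) + 1]] <- fit_at(st$current, st$lagged, lb, lk)
  sel <- select_ebic(fits, gamma = 0)
  # independent BIC computation
  bic <- vapply(fits, function(f) {
    E <- sum(f$B != 0) + sum(f$K[upper.tri(f$K)] != 0)
    -2 * f$loglik + E * log(f$n)
  }, numeric(1))
  expect_equal(sel$ebic, min(bic))
  expect_equal(sel$lambda_kappa, fits[[which.min(bic)]]$lambda_kappa)
  # single candidate passes through
  one <- select_ebic(fits[3], gamma = 0)
  expect_equal(one$lambda_beta, fits[[3]]$lambda_beta)
})

test_that("estimate_network is deterministic and supports node subsets", {
  y <- simulate_gvar_series(default_temporal(9), default_precision(9), 120,
                            seed = 10)
  colnames(y) <- paste0("f", 1:9)
  f1 <- estimate_network(y, config = quick_cfg())
  f2 <- estimate_network(y, config = quick_cfg())
  expect_identical(f1$omega, f2$omega)

  sub <- estimate_network(y, nodes = paste0("f", c(1:4, 6:9)),
                          config = quick_cfg())
  expect_equal(length(sub$node_names), 8)
  expect_true(all(is.finite(sub$omega)))
  expect_error(estimate_network(y, nodes = "nope", config = quick_cfg()),
               "unknown node")
})

test_that("shrinkage is monotone and omega always well-formed", {
  y <- simulate_gvar_series(default_temporal(6), default_precision(6), 150,
                            seed = 11)
  pr <- make_lag_pairs(y)
  st <- standardise_series(pr$current, pr$lagged)
  g <- lambda_grid(st$current, st$lagged, fit_config(n_lambda = 6))
  nnz_prev <- Inf
  for (lk in rev(g$kappa)) {         # increasing lambda_kappa
    f <- fit_at(st$current, st$lagged, g$beta[3], lk)
    nnz <- sum(f$K[upper.tri(f$K)] != 0)
    omega <- pcc_from_precision(f$K)
    expect_true(isSymmetric(omega))
    expect_lte(max(abs(omega)), 1)
    if (is.finite(nnz_prev)) expect_lte(nnz, nnz_prev)
    nnz_prev <- nnz
  }
})

test_that("edge-recovery F1 does not degrade as T grows", {
  truth <- abs(pcc_from_precision(recovery_precision())) > 1e-8
  ut <- upper.tri(truth)
  f1_at <- function(T_len, seeds) mean(vapply(seeds, function(s) {
    y <- simulate_gvar_series(default_temporal(9), recovery_precision(),
                              T_len, seed = s)
    est <- abs(estimate_network(y, config = quick_cfg())$omega) > 1e-8
    tp <- sum(est[ut] & truth[ut])
    if (tp == 0) return(0)
    prec <- tp / sum(est[ut]); rec <- tp / sum(truth[ut])
    2 * prec * rec / (prec + rec)
  }, numeric(1)))
  f1_small <- f1_at(60, 1:8)
  f1_large <- f1_at(400, 1:8)
  expect_gte(f1_large, f1_small)
  expect_gt(f1_large, 0.8)
})
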