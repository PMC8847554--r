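#' Estimation settings for personalised GVAR networks
#'
#' @param n_lambda Number of penalty values per grid dimension. The temporal
#'   (`lambda_beta`) and contemporaneous (`lambda_kappa`) penalties each get a
#'   log-spaced grid of this length and all `n_lambda^2` pairs are fitted.
#' @param gamma EBIC hyperparameter; 0 reduces the criterion to the BIC and
#'   prefers denser networks, which is the convention used throughout.
#' @param lambda_min_ratio Smallest grid value as a fraction of the largest.
#' @param pairing_policy `"concatenate"` pairs consecutive observed rows even
#'   across calendar gaps (missing days are simply absent); `"calendar"` only
#'   pairs rows one calendar day apart.
#' @param max_iterations,tolerance Outer alternation control for one fit.
#' @param standardise Z-score each node using the person's full-series
#'   mean/SD before fitting.
#' @param refit After EBIC selection, re-estimate B and K unpenalised on the
#'   selected support (zero pattern kept fixed). Unshrunk edge weights mirror
#'   the reference tooling's refit convention; they are noticeably inflated
#'   on short series, which matters for day-count bias analyses.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_lambda = 10, gamma = 0, lambda_min_ratio = 0.01,
                       pairing_policy = c("concatenate", "calendar"),
                       max_iterations = 100, tolerance = 1e-4,
                       standardise = TRUE, refit = FALSE) {
  pairing_policy <- match.arg(pairing_policy)
  stopifnot(n_lambda >= 1, gamma >= 0,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            max_iterations >= 1, tolerance > 0)
  structure(list(n_lambda = as.integer(n_lambda), gamma = gamma,
                 lambda_min_ratio = lambda_min_ratio,
                 pairing_policy = pairing_policy,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, standardise = isTRUE(standardise),
                 refit = isTRUE(refit)),
            class = "fit_config")
}

#' Build (current, lagged) row pairs from a daily series
#'
#' @param x Numeric matrix of ordered daily rows, or a
#'   [daily_feature_matrix()].
#' @param policy `"concatenate"` pairs consecutive observed rows regardless of
#'   calendar gaps; `"calendar"` keeps only pairs of truly adjacent days
#'   (requires `dates`).
#' @param dates Optional `Date` vector, one per row; taken from `x` when it is
#'   a `daily_feature_matrix`.
#' @return List with matrices `current` and `lagged` (both n_pairs x p).
#' @export
make_lag_pairs <- function(x, policy = c("concatenate", "calendar"),
                           dates = NULL) {
  policy <- match.arg(policy)
  if (inherits(x, "daily_feature_matrix")) {
    dates <- x$dates
    x <- x$values
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("insufficient data: need at least 2 rows to form lag pairs")
  if (policy == "calendar") {
    if (is.null(dates)) stop("calendar pairing requires row dates")
    keep <- which(diff(as.integer(as.Date(dates))) == 1L)
  } else {
    keep <- seq_len(nrow(x) - 1L)
  }
  if (length(keep) < 2)
    stop("insufficient data: fewer than 2 usable lag pairs under policy '",
         policy, "'")
  list(current = x[keep + 1L, , drop = FALSE],
       lagged  = x[keep, , drop = FALSE])
}

#' Z-score a lag-pair set with the person's full-series statistics
#'
#' By default the full observed series is reconstructed as the lagged rows
#' plus the final current row (exact under concatenate pairing) and its column
#' means/SDs standardise both matrices.
#'
#' @param current,lagged Matrices from [make_lag_pairs()].
#' @param center,scale Optional externally supplied per-column statistics.
#' @return List `current`, `lagged`, `center`, `scale`.
#' @export
standardise_series <- function(current, lagged, center = NULL, scale = NULL) {
  full <- rbind(lagged, current[nrow(current), , drop = FALSE])
  if (is.null(center)) center <- colMeans(full)
  if (is.null(scale)) scale <- apply(full, 2, sd)
  bad <- which(scale < 1e-12)
  if (length(bad)) {
    nm <- colnames(current)
    nm <- if (is.null(nm)) as.character(bad) else nm[bad]
    stop("zero-variance node(s): ", paste(nm, collapse = ", "))
  }
  list(current = sweep(sweep(current, 2, center), 2, scale, "/"),
       lagged  = sweep(sweep(lagged, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Penalty grids for the GVAR fit
#'
#' The `lambda_kappa` grid is log-spaced from the largest absolute off-diagonal
#' of the lag-0 covariance (the residual covariance under B = 0) down to that
#' times `lambda_min_ratio`; the `lambda_beta` grid likewise from
#' `max |lagged' current| / n`, rescaled per response by its lag-0 variance so
#' that the grid maximum is the exact threshold at which B vanishes.
#'
#' @param current,lagged Standardised lag-pair matrices.
#' @param config A [fit_config()].
#' @return List `beta` and `kappa`, each a decreasing numeric vector.
#' @export
lambda_grid <- function(current, lagged, config = fit_config()) {
  n <- nrow(current)
  syy <- crossprod(current) / n
  sxy <- crossprod(lagged, current) / n
  kappa_max <- max(abs(syy[upper.tri(syy)]), 0)
  # smallest penalty with B = 0 at the fully shrunk K (K_ii = 1/s_ii), so the
  # joint grid maximum provably yields the empty network
  beta_max <- max(sweep(abs(sxy), 2, pmax(diag(syy), 1e-12), "/"))
  logspace <- function(mx) {
    if (mx < 1e-12) {
      message("degenerate cross-products; penalty grid collapsed to {0}")
      return(0)
    }
    exp(seq(log(mx), log(mx * config$lambda_min_ratio),
            length.out = config$n_lambda))
  }
  list(beta = logspace(beta_max), kappa = logspace(kappa_max))
}

#' Fit the GVAR at one penalty pair
#'
#' Alternates a precision-weighted lasso update of the temporal matrix B with
#' a graphical-lasso update of the innovation precision K on the residual
#' covariance, to convergence in max-abs parameter change.
#'
#' @param current,lagged Standardised lag-pair matrices.
#' @param lambda_beta,lambda_kappa Penalties on entries of B and on
#'   off-diagonals of K.
#' @param config A [fit_config()].
#' @param B0,K0 Optional warm starts.
#' @return List with `B`, `K`, `loglik`, `converged`, `jittered`,
#'   `lambda_beta`, `lambda_kappa`, `n`.
#' @export
fit_at <- function(current, lagged, lambda_beta, lambda_kappa,
                   config = fit_config(), B0 = NULL, K0 = NULL) {
  n <- nrow(current)
  p <- ncol(current)
  sxx <- crossprod(lagged) / n
  sxy <- crossprod(lagged, current) / n
  syy <- crossprod(current) / n
  if (is.null(B0)) B0 <- matrix(0, p, p)
  if (is.null(K0)) K0 <- diag(1 / pmax(diag(syy), 1e-8), p)
  res <- .gvar_fit_cpp(sxx, sxy, syy, n, lambda_beta, lambda_kappa,
                       B0, K0, config$max_iterations, config$tolerance)
  if (res$jittered)
    message("near-singular residual covariance; ridge jitter applied")
  res$lambda_beta <- lambda_beta
  res$lambda_kappa <- lambda_kappa
  res$n <- n
  res
}

ebic_value <- function(fit, gamma, p) {
  nz <- sum(fit$B != 0) + sum(fit$K[upper.tri(fit$K)] != 0)
  n_params <- p^2 + p * (p - 1) / 2
  -2 * fit$loglik + nz * log(fit$n) + 4 * gamma * nz * log(n_params)
}

#' Select the EBIC-optimal fit over a penalty grid
#'
#' At `gamma = 0` the criterion is the BIC, counting as parameters the
#' nonzero entries of B plus the nonzero upper-triangle off-diagonals of K.
#' Ties are broken toward the smaller penalty pair (the denser model).
#'
#' @param fits List of fits from [fit_at()].
#' @param gamma EBIC hyperparameter.
#' @param node_names Optional node labels for the returned object.
#' @return A `gvar_fit` object (see [estimate_network()]).
#' @export
select_ebic <- function(fits, gamma = 0, node_names = NULL) {
  stopifnot(length(fits) >= 1)
  p <- ncol(fits[[1]]$B)
  ebics <- vapply(fits, ebic_value, numeric(1), gamma = gamma, p = p)
  lb <- vapply(fits, `[[`, numeric(1), "lambda_beta")
  lk <- vapply(fits, `[[`, numeric(1), "lambda_kappa")
  best <- order(ebics, lk, lb)[1]
  fit <- fits[[best]]
  new_gvar_fit(fit, ebic = ebics[best], node_names = node_names)
}

new_gvar_fit <- function(fit, ebic, node_names = NULL) {
  p <- ncol(fit$B)
  if (is.null(node_names)) node_names <- paste0("V", seq_len(p))
  B <- fit$B; K <- fit$K
  dimnames(B) <- dimnames(K) <- list(node_names, node_names)
  omega <- pcc_from_precision(K)
  structure(list(node_names = node_names, beta = B, kappa = K, omega = omega,
                 lambda_beta = fit$lambda_beta, lambda_kappa = fit$lambda_kappa,
                 ebic = unname(ebic), loglik = fit$loglik, n_days = fit$n + 1L,
                 n_pairs = fit$n, converged = isTRUE(fit$converged)),
            class = "gvar_fit")
}

#' @export
print.gvar_fit <- function(x, ...) {
  cat("Personalised GVAR fit:", length(x$node_names), "nodes,",
      x$n_pairs, "lag pairs\n")
  cat(sprintf("  lambda_beta = %.4g, lambda_kappa = %.4g, EBIC = %.2f%s\n",
              x$lambda_beta, x$lambda_kappa, x$ebic,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  contemporaneous edges: %d nonzero of %d\n",
              sum(x$omega[upper.tri(x$omega)] != 0),
              sum(upper.tri(x$omega))))
  invisible(x)
}

#' Partial correlations from a precision matrix
#'
#' `omega_ij = -kappa_ij / sqrt(kappa_ii * kappa_jj)`, zero diagonal.
#'
#' @param K Symmetric positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations in \[-1, 1\].
#' @export
pcc_from_precision <- function(K) {
  K <- as.matrix(K)
  if (!isSymmetric(unname(K), tol = 1e-8))
    stop("precision matrix must be symmetric")
  if (any(eigen(K, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("precision matrix must be positive definite")
  d <- sqrt(diag(K))
  omega <- -K / tcrossprod(d)
  diag(omega) <- 0
  (omega + t(omega)) / 2
}

#' Estimate a personalised GVAR network with EBIC selection
#'
#' End-to-end per-person estimator: optional node subsetting, full-series
#' standardisation, lag-pair construction, a `n_lambda x n_lambda` penalty
#' grid with warm starts, and EBIC (gamma = 0, i.e. BIC) selection.
#'
#' @param x A [daily_feature_matrix()] or a numeric matrix of ordered daily
#'   rows (columns = nodes).
#' @param nodes Optional character vector of node names (column subset).
#' @param config A [fit_config()].
#' @param dates Optional per-row dates when `x` is a plain matrix.
#' @return A `gvar_fit` with elements `node_names`, `beta` (temporal matrix),
#'   `kappa` (innovation precision), `omega` (contemporaneous partial
#'   correlations), selected penalties, `ebic`, `n_days`, `converged`.
#' @export
estimate_network <- function(x, nodes = NULL, config = fit_config(),
                             dates = NULL) {
  if (inherits(x, "daily_feature_matrix")) {
    dates <- x$dates
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!is.null(nodes)) {
    missing_nodes <- setdiff(nodes, colnames(x))
    if (length(missing_nodes))
      stop("unknown node(s): ", paste(missing_nodes, collapse = ", "))
    x <- x[, nodes, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 nodes")
  n_days <- nrow(x)

  if (config$standardise) {
    mu <- colMeans(x)
    sdev <- apply(x, 2, sd)
    bad <- which(sdev < 1e-12)
    if (length(bad))
      stop("zero-variance node(s): ", paste(colnames(x)[bad], collapse = ", "))
    x <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  }

  pairs <- make_lag_pairs(x, policy = config$pairing_policy, dates = dates)
  grid <- lambda_grid(pairs$current, pairs$lagged, config)

  n <- nrow(pairs$current)
  p <- ncol(x)
  sxx <- crossprod(pairs$lagged) / n
  sxy <- crossprod(pairs$lagged, pairs$current) / n
  syy <- crossprod(pairs$current) / n

  fits <- vector("list", length(grid$beta) * length(grid$kappa))
  idx <- 0L
  B_warm <- matrix(0, p, p)
  K_warm <- diag(1 / pmax(diag(syy), 1e-8), p)
  for (lb in grid$beta) {        # descending: warm starts along the path
    B_col <- B_warm; K_col <- K_warm
    first_in_col <- TRUE
    for (lk in grid$kappa) {
      res <- .gvar_fit_cpp(sxx, sxy, syy, n, lb, lk, B_col, K_col,
                           config$max_iterations, config$tolerance)
      res$lambda_beta <- lb
      res$lambda_kappa <- lk
      res$n <- n
      idx <- idx + 1L
      fits[[idx]] <- res
      B_col <- res$B; K_col <- res$K
      if (first_in_col) { B_warm <- res$B; K_warm <- res$K; first_in_col <- FALSE }
    }
  }
  out <- select_ebic(fits, gamma = config$gamma, node_names = colnames(x))
  out$n_days <- n_days
  if (config$refit) {
    rf <- .gvar_refit_cpp(sxx, sxy, syy, n,
                          (out$beta != 0) * 1L,
                          (out$kappa != 0 & row(out$kappa) != col(out$kappa)) * 1L)
    B <- rf$B; K <- rf$K
    dimnames(B) <- dimnames(K) <- list(out$node_names, out$node_names)
    out$beta <- B
    out$kappa <- K
    out$omega <- pcc_from_precision(K)
    out$loglik <- rf$loglik
    out$refit <- TRUE
  }
  out
}
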