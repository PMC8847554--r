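#' Combine severity scores from different scales into one z-score
#'
#' Each scale is standardised by its own mean and standard deviation and the
#' standardised scores are pooled into a single severity column.
#'
#' @param scores `data.frame` with `user_id`, `scale`, `score`.
#' @return `data.frame` with `user_id`, `severity_z`.
#' @export
combine_severity <- function(scores) {
  stopifnot(all(c("user_id", "scale", "score") %in% names(scores)))
  out <- lapply(split(scores, scores$scale), function(sub) {
    if (nrow(sub) < 2)
      stop("scale '", sub$scale[1], "' has fewer than 2 users; cannot standardise")
    s <- sd(sub$score)
    if (s < 1e-12) stop("scale '", sub$scale[1], "' has zero variance")
    data.frame(user_id = sub$user_id,
               severity_z = (sub$score - mean(sub$score)) / s,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(scores$user_id, res$user_id), , drop = FALSE]
}

#' 3-SD outliers among per-user feature means
#'
#' Same single-pass rule as [strength_outlier_mask()], applied to 12-month
#' per-user feature means.
#'
#' @param feature_means Users x features matrix of means.
#' @param threshold_sd Threshold (default 3).
#' @return Logical matrix, `TRUE` = excluded.
#' @export
mean_feature_outliers <- function(feature_means, threshold_sd = 3) {
  strength_outlier_mask(feature_means, threshold_sd)
}

effect_row <- function(term, beta, se, p, model, n) {
  data.frame(term = term, beta = beta, se = se, p_value = p, model = model,
             n = n, stringsAsFactors = FALSE)
}

#' Per-feature association with severity
#'
#' Uncorrected two-sided Pearson correlation plus the slope of a simple
#' regression of severity on the standardised feature mean, per feature.
#' Outliers should already be masked (`NA`s are dropped pairwise).
#'
#' @param feature_means Users x features matrix (masked cells `NA`).
#' @param severity Numeric severity z-scores, one per user.
#' @return `data.frame` with one row per feature: `feature`, `r`, `beta`,
#'   `se`, `p_value`, `n`.
#' @export
feature_severity_association <- function(feature_means, severity) {
  feature_means <- as.matrix(feature_means)
  stopifnot(nrow(feature_means) == length(severity))
  feats <- colnames(feature_means)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(feature_means)))
  rows <- lapply(seq_len(ncol(feature_means)), function(j) {
    x <- feature_means[, j]
    ok <- is.finite(x) & is.finite(severity)
    x <- x[ok]; y <- severity[ok]
    if (sd(x) < 1e-12) {
      message("feature ", feats[j], " is constant; no association computed")
      return(data.frame(feature = feats[j], r = NA_real_, beta = NA_real_,
                        se = NA_real_, p_value = NA_real_, n = length(x),
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(x, y)
    fit <- summary(lm(y ~ scale(x)))$coefficients
    data.frame(feature = feats[j], r = unname(ct$estimate),
               beta = fit[2, 1], se = fit[2, 2], p_value = ct$p.value,
               n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress strength centralities on depression severity
#'
#' Ordinary least squares of global strength (and each node strength) on
#' severity, optionally controlling for the number of observed days.
#'
#' @param strengths Users x nodes matrix of node strengths (masked cells
#'   `NA`).
#' @param severity Numeric severity per user.
#' @param n_days Optional per-user day counts used as covariate.
#' @param covariates `"none"` or `"n_days"`.
#' @return `data.frame` of effect rows (`term` = "global" or node name) with
#'   `beta`, `se`, `p_value`, `model`, `n`.
#' @export
severity_strength_regression <- function(strengths, severity, n_days = NULL,
                                         covariates = c("none", "n_days")) {
  covariates <- match.arg(covariates)
  strengths <- as.matrix(strengths)
  stopifnot(nrow(strengths) == length(severity))
  if (sd(severity, na.rm = TRUE) < 1e-12)
    stop("severity is constant; regression undefined")
  if (covariates == "n_days") stopifnot(!is.null(n_days))
  fit_one <- function(y, label) {
    dat <- data.frame(y = y, severity = severity)
    form <- y ~ severity
    if (covariates == "n_days") { dat$n_days <- n_days; form <- y ~ severity + n_days }
    dat <- dat[complete.cases(dat), , drop = FALSE]
    co <- summary(lm(form, data = dat))$coefficients
    effect_row(label, co["severity", 1], co["severity", 2], co["severity", 4],
               paste0("ols(", deparse(form), ")"), nrow(dat))
  }
  gl <- rowMeans(strengths, na.rm = TRUE)
  out <- fit_one(gl, "global")
  for (j in seq_len(ncol(strengths)))
    out <- rbind(out, fit_one(strengths[, j],
                              colnames(strengths)[j] %||% paste0("V", j)))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split-half reliability of mean edge strengths
#'
#' Randomly splits users into two equal halves, averages each half's
#' partial-correlation networks, and correlates the two mean networks over
#' the p(p-1)/2 unique edges. Optionally recomputed with the strongest edge
#' excluded.
#'
#' @param networks List of per-user partial-correlation matrices (or
#'   `gvar_fit`s).
#' @param seed Integer seed for the half-split.
#' @param drop_strongest Also report the correlation excluding the edge with
#'   the largest mean absolute weight.
#' @return List with `r`, `n_edges`, and (optionally) `r_excl_strongest`.
#' @export
split_half_edge_reliability <- function(networks, seed = 1L,
                                        drop_strongest = TRUE) {
  if (length(networks) < 4) stop("need at least 4 users for a split-half")
  mats <- lapply(networks, function(x)
    if (inherits(x, "gvar_fit")) x$omega else as.matrix(x))
  set.seed(seed)
  n <- length(mats)
  half <- sample.int(n, floor(n / 2))
  m1 <- mean_network(mats[half])
  m2 <- mean_network(mats[setdiff(seq_len(n), half)])
  ut <- upper.tri(m1)
  e1 <- m1[ut]; e2 <- m2[ut]
  out <- list(r = safe_cor(e1, e2), n_edges = sum(ut))
  if (drop_strongest) {
    strongest <- which.max(abs(e1 + e2) / 2)
    out$r_excl_strongest <- safe_cor(e1[-strongest], e2[-strongest])
  }
  out
}

#' Partition features into depression-relevant and irrelevant pools
#'
#' A feature is relevant iff its uncorrected two-sided Pearson p-value
#' against severity is below `alpha`. Constant features are forced into the
#' irrelevant pool with a warning.
#'
#' @param feature_means Users x features matrix (masked cells `NA`).
#' @param severity Numeric severity per user.
#' @param alpha Threshold (default 0.05).
#' @return `data.frame` of class `feature_pools` with `feature`, `r`,
#'   `p_value`, `pool`.
#' @export
build_feature_pools <- function(feature_means, severity, alpha = 0.05) {
  assoc <- feature_severity_association(feature_means, severity)
  pool <- ifelse(!is.na(assoc$p_value) & assoc$p_value < alpha,
                 "relevant", "irrelevant")
  if (any(is.na(assoc$p_value)))
    warning("constant/degenerate feature(s) assigned to the irrelevant pool: ",
            paste(assoc$feature[is.na(assoc$p_value)], collapse = ", "))
  out <- data.frame(feature = assoc$feature, r = assoc$r,
                    p_value = assoc$p_value, pool = pool,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("feature_pools", class(out))
  out
}
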