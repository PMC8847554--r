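#' Fit separate within- and outside-episode networks for one user
#'
#' The within fit uses only days labelled `"within"`, the outside fit only
#' `"outside"` days; lag pairs are built inside each day set. Users failing
#' the 15/15 paired eligibility rule are excluded (returns `NULL` with a
#' message).
#'
#' @param matrix A [daily_feature_matrix()] or numeric series matrix.
#' @param labels Day labels from [label_days()].
#' @param config A [fit_config()].
#' @param min_paired_days Minimum days per period (default 15).
#' @return List of class `paired_networks` with `within_fit`, `outside_fit`,
#'   `n_days_within`, `n_days_outside`, or `NULL` when ineligible.
#' @export
fit_paired_networks <- function(matrix, labels, config = fit_config(),
                                min_paired_days = 15L) {
  uid <- if (inherits(matrix, "daily_feature_matrix")) matrix$user_id else NA
  vals <- if (inherits(matrix, "daily_feature_matrix")) matrix$values else
    as.matrix(matrix)
  dates <- if (inherits(matrix, "daily_feature_matrix")) matrix$dates else NULL
  stopifnot(length(labels) == nrow(vals))
  elig <- check_eligibility(nrow(vals), labels, mode = "paired",
                            min_paired_days = min_paired_days)
  if (!elig$eligible) {
    message("user ", uid, " ineligible for paired analysis (",
            elig$n_within, " within / ", elig$n_outside, " outside)")
    return(NULL)
  }
  w <- labels == "within"
  fit_part <- function(rows) {
    estimate_network(vals[rows, , drop = FALSE], config = config,
                     dates = if (is.null(dates)) NULL else dates[rows])
  }
  res <- tryCatch(
    list(within = fit_part(which(w)), outside = fit_part(which(!w))),
    error = function(e) {
      message("user ", uid, " excluded: ", conditionMessage(e))
      NULL
    })
  if (is.null(res)) return(NULL)
  structure(list(user_id = uid, within_fit = res$within,
                 outside_fit = res$outside,
                 n_days_within = elig$n_within,
                 n_days_outside = elig$n_outside),
            class = "paired_networks")
}

#' Stack paired networks into a two-rows-per-user analysis table
#'
#' @param paired List of `paired_networks` (NULLs dropped).
#' @return `data.frame` with `user_id`, `period`, `episode` (1 = within),
#'   `global_strength`, one column per node strength, `n_days`.
#' @export
paired_strength_table <- function(paired) {
  paired <- Filter(Negate(is.null), paired)
  stopifnot(length(paired) >= 1)
  rows <- lapply(paired, function(pn) {
    sw <- node_strength(pn$within_fit)
    so <- node_strength(pn$outside_fit)
    base <- data.frame(user_id = rep(pn$user_id, 2),
                       period = c("within", "outside"),
                       episode = c(1L, 0L),
                       global_strength = c(mean(sw), mean(so)),
                       n_days = c(pn$n_days_within, pn$n_days_outside),
                       stringsAsFactors = FALSE)
    cbind(base, rbind(sw, so))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mask 3-SD strength outliers in a paired analysis table
#'
#' Within each period group (within/outside), strength values more than
#' `threshold_sd` standard deviations from the group mean are set to `NA`,
#' mirroring the group-level exclusion applied before the severity and
#' episode regressions. Users losing a value drop out of [episode_effect()]
#' pairwise.
#'
#' @param table A [paired_strength_table()].
#' @param columns Strength columns to mask (default `"global_strength"`).
#' @param threshold_sd Threshold (default 3).
#' @return The table with masked cells set to `NA`.
#' @export
mask_paired_strengths <- function(table, columns = "global_strength",
                                  threshold_sd = 3) {
  for (col in columns) {
    for (per in unique(table$period)) {
      rows <- table$period == per
      x <- table[[col]][rows]
      mu <- mean(x, na.rm = TRUE)
      sdev <- sd(x, na.rm = TRUE)
      if (is.finite(sdev) && sdev > 0)
        table[[col]][rows][abs(x - mu) > threshold_sd * sdev] <- NA
    }
  }
  table
}

#' Within-subject episode effect on network strength
#'
#' Linear model on the stacked two-rows-per-user table with fixed per-user
#' intercepts and a within-subject episode indicator (1 = within episode).
#' With no covariates the episode coefficient equals the mean paired
#' difference exactly.
#'
#' @param table A [paired_strength_table()] (strength outlier masks, if any,
#'   applied beforehand by setting cells to `NA`).
#' @param outcome `"global_strength"` or a node column name.
#' @param covariates `"none"`, `"n_days"`, or `"n_days_plus_interaction"`.
#' @return One effect row: `term = "episode"`, `beta`, `se`, `p_value`,
#'   `model`, `n` (number of users).
#' @export
episode_effect <- function(table, outcome = "global_strength",
                           covariates = c("none", "n_days",
                                          "n_days_plus_interaction")) {
  covariates <- match.arg(covariates)
  stopifnot(outcome %in% names(table))
  dat <- data.frame(user = factor(table$user_id), episode = table$episode,
                    y = table[[outcome]], n_days = table$n_days)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  dat <- dat[dat$user %in% names(which(table(dat$user) == 2)), , drop = FALSE]
  dat$user <- droplevels(dat$user)
  if (nlevels(dat$user) < 2) stop("need at least 2 users with complete pairs")
  form <- switch(covariates,
                 none = y ~ 0 + user + episode,
                 n_days = y ~ 0 + user + episode + n_days,
                 n_days_plus_interaction = y ~ 0 + user + episode + n_days +
                   episode:n_days)
  co <- summary(lm(form, data = dat))$coefficients
  effect_row("episode", co["episode", 1], co["episode", 2],
             co["episode", 4],
             paste0("within-subject ols, covariates = ", covariates),
             nlevels(dat$user))
}

#' Paired Wilcoxon signed-rank test of within vs outside strengths
#'
#' @param within,outside Paired numeric vectors (e.g. global strengths).
#' @return List with `V`, `p_value`, `n_nonzero`.
#' @export
wilcoxon_paired <- function(within, outside) {
  stopifnot(length(within) == length(outside))
  d <- within - outside
  if (all(d == 0)) {
    warning("all paired differences are zero; test degenerate")
    return(list(V = 0, p_value = 1, n_nonzero = 0L))
  }
  wt <- suppressWarnings(wilcox.test(within, outside, paired = TRUE))
  list(V = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = sum(d != 0))
}

#' Subsample bootstrap of the episode effect
#'
#' Each draw subsamples `ceiling(fraction * n)` users without replacement and
#' recomputes the episode effect on the precomputed strengths.
#'
#' @param table A [paired_strength_table()].
#' @param fraction Subsample fraction (default 0.8).
#' @param n_boot Number of draws (default 1000).
#' @param seed Integer seed.
#' @param outcome,covariates Passed to [episode_effect()].
#' @return List with `betas`, `mean`, `se` (SD of the distribution), and
#'   `p_exceed_zero` (one-sided share of draws at or below zero).
#' @export
bootstrap_effect <- function(table, fraction = 0.8, n_boot = 1000, seed = 1L,
                             outcome = "global_strength",
                             covariates = "none") {
  users <- unique(table$user_id)
  if (length(users) < 5) stop("need at least 5 users")
  set.seed(seed)
  m <- ceiling(fraction * length(users))
  betas <- vapply(seq_len(n_boot), function(b) {
    keep <- sample(users, m)
    episode_effect(table[table$user_id %in% keep, , drop = FALSE],
                   outcome = outcome, covariates = covariates)$beta
  }, numeric(1))
  list(betas = betas, mean = mean(betas), se = sd(betas),
       p_exceed_zero = mean(betas <= 0))
}

#' Day-label permutation null for the episode effect
#'
#' Per permutation and per user, a uniformly random subset of the user's
#' observed days of size `n_days_within` is relabelled as (fake) within
#' episode — preserving each user's within/outside day counts exactly — and
#' both networks are re-estimated before recomputing the episode effect.
#' The mean of the null distribution exposes the day-count bias: networks
#' fitted on fewer days tend to look more connected.
#'
#' @param matrices Named list of [daily_feature_matrix()] (or numeric
#'   matrices), one per user.
#' @param labels Named list of day-label vectors (from [label_days()]).
#' @param config A [fit_config()].
#' @param n_perm Number of permutations (default 1000; 200 is a desk-scale
#'   choice).
#' @param seed Integer seed.
#' @param outcome,covariates Passed to [episode_effect()].
#' @param max_redraw Re-draws allowed when a permuted fit fails.
#' @return List of class `permutation_result`: `observed_beta`, `null_betas`,
#'   `null_mean`, `empirical_p` = (1 + #\{null >= observed\}) / (n_perm + 1).
#' @export
permutation_null <- function(matrices, labels, config = fit_config(),
                             n_perm = 1000, seed = 1L,
                             outcome = "global_strength",
                             covariates = "none", max_redraw = 10L) {
  stopifnot(length(matrices) == length(labels))
  users <- names(matrices)
  if (is.null(users)) users <- paste0("u", seq_along(matrices))

  vals <- lapply(matrices, function(m)
    if (inherits(m, "daily_feature_matrix")) m$values else as.matrix(m))
  n_within <- vapply(labels, function(l) sum(l == "within"), integer(1))
  n_total <- vapply(vals, nrow, integer(1))

  fit_pair_strengths <- function(v, w) {
    fw <- estimate_network(v[w, , drop = FALSE], config = config)
    fo <- estimate_network(v[!w, , drop = FALSE], config = config)
    c(within = global_strength(fw), outside = global_strength(fo))
  }
  make_table <- function(strengths) {
    do.call(rbind, lapply(seq_along(users), function(i)
      data.frame(user_id = rep(users[i], 2), period = c("within", "outside"),
                 episode = c(1L, 0L),
                 global_strength = unname(strengths[[i]]),
                 n_days = c(n_within[i], n_total[i] - n_within[i]),
                 stringsAsFactors = FALSE)))
  }

  obs <- lapply(seq_along(users), function(i)
    fit_pair_strengths(vals[[i]], labels[[i]] == "within"))
  observed_beta <- episode_effect(make_table(obs), outcome = outcome,
                                  covariates = covariates)$beta

  set.seed(seed)
  null_betas <- numeric(n_perm)
  n_redrawn <- 0L
  for (b in seq_len(n_perm)) {
    strengths <- vector("list", length(users))
    for (i in seq_along(users)) {
      for (attempt in seq_len(max_redraw)) {
        fake <- rep(FALSE, n_total[i])
        fake[sample.int(n_total[i], n_within[i])] <- TRUE
        s <- tryCatch(fit_pair_strengths(vals[[i]], fake),
                      error = function(e) NULL)
        if (!is.null(s)) break
        n_redrawn <- n_redrawn + 1L
      }
      if (is.null(s)) stop("permutation draw failed repeatedly for user ",
                           users[i])
      strengths[[i]] <- s
    }
    null_betas[b] <- episode_effect(make_table(strengths), outcome = outcome,
                                    covariates = covariates)$beta
  }
  if (n_redrawn > 0) message(n_redrawn, " permutation draw(s) redrawn")
  structure(list(observed_beta = observed_beta, null_betas = null_betas,
                 null_mean = mean(null_betas),
                 empirical_p = (1 + sum(null_betas >= observed_beta)) /
                   (n_perm + 1)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation null: observed beta = %.4f, null mean = %.4f, p = %.4f (%d perms)\n",
    x$observed_beta, x$null_mean, x$empirical_p, length(x$null_betas)))
  invisible(x)
}

#' Paired within/outside networks for a whole synthetic cohort
#'
#' Convenience wrapper: labels each user's observed days from the true
#' episode calendar, applies paired eligibility, and fits both networks.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config A [fit_config()].
#' @param min_paired_days Eligibility threshold (default 15).
#' @return List with `paired` (per eligible user), `table`
#'   ([paired_strength_table()]), `matrices` and `labels` for the eligible
#'   users (for [permutation_null()]).
#' @export
cohort_paired_analysis <- function(cohort, config = fit_config(),
                                   min_paired_days = 15L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  paired <- list(); mats <- list(); labs <- list()
  for (u in cohort$users) {
    lab <- label_days(u$episodes, u$features)
    pn <- suppressMessages(
      fit_paired_networks(u$features, lab, config = config,
                          min_paired_days = min_paired_days))
    if (is.null(pn)) next
    paired[[u$user_id]] <- pn
    mats[[u$user_id]] <- u$features
    labs[[u$user_id]] <- lab
  }
  if (!length(paired)) stop("no eligible users in cohort")
  list(paired = paired, table = paired_strength_table(paired),
       matrices = mats, labels = labs)
}
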