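#' Sample random feature sets from a pool
#'
#' Each set is `k` distinct features drawn uniformly without replacement
#' (sets may repeat across draws).
#'
#' @param pool Character vector of feature names.
#' @param k Features per set (default 9).
#' @param n_sets Number of sets (default 1000).
#' @param seed Integer seed.
#' @return List of character vectors.
#' @export
sample_feature_sets <- function(pool, k = 9, n_sets = 1000, seed = 1L) {
  if (length(pool) < k)
    stop("pool has ", length(pool), " features; need at least ", k)
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) sample(pool, k))
}

#' Episode effect for each sampled feature set
#'
#' For every set, the full paired within/outside pipeline runs on networks
#' restricted to that set's nodes and the day-count-adjusted episode effect
#' is recorded. Per-set failures are logged and excluded.
#'
#' @param sets List of feature-name vectors (from [sample_feature_sets()]).
#' @param cohort A [simulate_cohort()] result (or a list with `matrices` and
#'   `labels` as in [cohort_paired_analysis()]).
#' @param config A [fit_config()].
#' @param pool_label Label stored with each result.
#' @param covariates Covariate spec for [episode_effect()] (default
#'   `"n_days"`).
#' @param min_paired_days Eligibility threshold (default 15).
#' @return `data.frame` with `set_id`, `pool`, `features` (joined by `|`),
#'   `beta`, `se`, `p_value`, `n_users`.
#' @export
episode_effect_per_set <- function(sets, cohort, config = fit_config(),
                                   pool_label = NA_character_,
                                   covariates = "n_days",
                                   min_paired_days = 15L) {
  if (inherits(cohort, "synthetic_cohort")) {
    mats <- lapply(cohort$users, `[[`, "features")
    labs <- lapply(cohort$users, function(u) label_days(u$episodes, u$features))
    names(mats) <- names(labs) <- vapply(cohort$users, `[[`, character(1),
                                         "user_id")
  } else {
    mats <- cohort$matrices
    labs <- cohort$labels
  }
  rows <- lapply(seq_along(sets), function(s) {
    nodes <- sets[[s]]
    paired <- list()
    for (uid in names(mats)) {
      m <- mats[[uid]]
      vals <- if (inherits(m, "daily_feature_matrix")) m$values else
        as.matrix(m)
      pn <- tryCatch(suppressMessages(
        fit_paired_networks(vals[, nodes, drop = FALSE], labs[[uid]],
                            config = config,
                            min_paired_days = min_paired_days)),
        error = function(e) NULL)
      if (!is.null(pn)) { pn$user_id <- uid; paired[[uid]] <- pn }
    }
    eff <- tryCatch(
      episode_effect(paired_strength_table(paired), covariates = covariates),
      error = function(e) {
        message("set ", s, " excluded: ", conditionMessage(e)); NULL
      })
    if (is.null(eff)) return(NULL)
    data.frame(set_id = s, pool = pool_label,
               features = paste(nodes, collapse = "|"),
               beta = eff$beta, se = eff$se, p_value = eff$p_value,
               n_users = eff$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Compare episode effects between feature pools
#'
#' Linear model of the per-set episode beta on a relevant-pool indicator.
#'
#' @param results Row-bound [episode_effect_per_set()] results covering both
#'   pools (`pool` in `"relevant"`, `"irrelevant"`).
#' @return One effect row for the pool indicator (`relevant` = 1).
#' @export
compare_pools <- function(results) {
  pools <- unique(results$pool)
  if (length(pools) < 2) stop("need results from both pools")
  dat <- data.frame(beta = results$beta,
                    relevant = as.integer(results$pool == "relevant"))
  co <- summary(lm(beta ~ relevant, data = dat))$coefficients
  effect_row("relevant_pool", co["relevant", 1], co["relevant", 2],
             co["relevant", 4], "ols(set beta ~ pool)", nrow(dat))
}

#' Top networks and feature inclusion frequencies
#'
#' Ranks relevant-pool sets by episode beta (descending) and reports how
#' often each feature appears among the top `top_n` sets.
#'
#' @param results [episode_effect_per_set()] results.
#' @param top_n Number of top sets (default 100).
#' @param pool Pool to rank within (default `"relevant"`; `NULL` ranks all).
#' @return List with `top_sets` (ranked `data.frame`) and `frequency`
#'   (`data.frame` of `feature`, `count`, `proportion`).
#' @export
top_network_report <- function(results, top_n = 100, pool = "relevant") {
  sub <- if (is.null(pool)) results else
    results[results$pool == pool, , drop = FALSE]
  if (nrow(sub) < top_n)
    stop("only ", nrow(sub), " sets available; need ", top_n)
  sub <- sub[order(-sub$beta), , drop = FALSE]
  top <- head(sub, top_n)
  feats <- unlist(strsplit(top$features, "|", fixed = TRUE))
  tab <- sort(table(feats), decreasing = TRUE)
  list(top_sets = top,
       frequency = data.frame(feature = names(tab),
                              count = as.integer(tab),
                              proportion = as.numeric(tab) / top_n,
                              stringsAsFactors = FALSE))
}
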