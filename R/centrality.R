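#' Node strength centrality
#'
#' Strength of node i is the sum of absolute contemporaneous partial
#' correlations incident to it.
#'
#' @param omega Partial-correlation matrix (zero diagonal) or a `gvar_fit`.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(omega) {
  if (inherits(omega, "gvar_fit")) omega <- omega$omega
  s <- rowSums(abs(omega)) - abs(diag(omega))
  names(s) <- rownames(omega)
  s
}

#' Global network strength
#'
#' The mean of node strengths across all nodes (this pipeline's convention).
#'
#' @param x Strength vector, partial-correlation matrix, or `gvar_fit`.
#' @return Scalar.
#' @export
global_strength <- function(x) {
  if (!is.null(dim(x)) || inherits(x, "gvar_fit")) x <- node_strength(x)
  mean(x)
}

#' Group-level 3-SD outlier mask for node strengths
#'
#' Flags, per (user, node), strength values more than `threshold_sd` standard
#' deviations from that node's group mean, in a single pass.
#'
#' @param strengths Users x nodes numeric matrix (e.g. stacked
#'   [node_strength()] vectors).
#' @param threshold_sd Threshold (default 3).
#' @return Logical matrix, `TRUE` = excluded.
#' @export
strength_outlier_mask <- function(strengths, threshold_sd = 3) {
  strengths <- as.matrix(strengths)
  if (nrow(strengths) < 3) stop("need at least 3 records to define outliers")
  mu <- colMeans(strengths)
  sdv <- apply(strengths, 2, sd)
  mask <- sweep(abs(sweep(strengths, 2, mu)), 2,
                pmax(sdv, .Machine$double.eps), "/") > threshold_sd
  mask & rep(sdv > 0, each = nrow(strengths))
}

#' Element-wise mean network over users
#'
#' @param networks List of partial-correlation matrices (or `gvar_fit`s) on
#'   the same node set.
#' @param mask Optional exclusion: a logical vector (length = users, `TRUE`
#'   drops the user) or a users x nodes matrix from
#'   [strength_outlier_mask()] (an edge is dropped for a user when either
#'   endpoint is masked).
#' @return Mean partial-correlation matrix.
#' @export
mean_network <- function(networks, mask = NULL) {
  if (!length(networks)) stop("empty network list")
  mats <- lapply(networks, function(x)
    if (inherits(x, "gvar_fit")) x$omega else as.matrix(x))
  p <- ncol(mats[[1]])
  acc <- matrix(0, p, p)
  wt <- matrix(0, p, p)
  for (u in seq_along(mats)) {
    if (is.null(mask)) {
      keep <- matrix(TRUE, p, p)
    } else if (is.matrix(mask)) {
      drop_node <- mask[u, ]
      keep <- outer(!drop_node, !drop_node, "&")
    } else {
      keep <- matrix(!mask[u], p, p)
    }
    acc <- acc + ifelse(keep, mats[[u]], 0)
    wt <- wt + keep
  }
  out <- acc / pmax(wt, 1)
  dimnames(out) <- dimnames(mats[[1]])
  out
}

#' Closeness and betweenness of a (mean) network
#'
#' Edge distances are `1 / |omega|`; zero edges are absent. Closeness for a
#' node disconnected from part of the graph is computed on its reachable set
#' and flagged.
#'
#' @param omega Partial-correlation matrix.
#' @return `data.frame` with `node`, `strength`, `closeness`, `betweenness`,
#'   `disconnected`.
#' @export
descriptive_centralities <- function(omega) {
  if (inherits(omega, "gvar_fit")) omega <- omega$omega
  p <- ncol(omega)
  nodes <- rownames(omega)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  adj <- abs(omega)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight   # distance = 1/|omega|
  d <- igraph::distances(g)
  disconnected <- apply(d, 1, function(z) any(!is.finite(z)))
  closeness <- vapply(seq_len(p), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) return(0)
    length(di) / sum(di)
  }, numeric(1))
  betw <- if (igraph::ecount(g) > 0) igraph::betweenness(g) else rep(0, p)
  if (any(disconnected))
    message("node(s) ", paste(nodes[disconnected], collapse = ", "),
            " cannot reach the whole network; closeness on reachable set")
  data.frame(node = nodes, strength = unname(node_strength(omega)),
             closeness = unname(closeness), betweenness = unname(betw),
             disconnected = unname(disconnected), stringsAsFactors = FALSE)
}

# correlation that degrades gracefully for constant vectors
safe_cor <- function(a, b) {
  if (sd(a) < 1e-12 || sd(b) < 1e-12) {
    if (max(abs(a - b)) < 1e-12) return(1)
    return(0)
  }
  cor(a, b)
}

#' Case-dropping stability of strength centralities
#'
#' Repeatedly drops up to `max_drop` of the observed days, refits the
#' network, and correlates the subsample node strengths with the full-sample
#' ones. The CS coefficient is the largest drop proportion whose
#' `1 - quantile` (default 5th) percentile correlation stays at or above
#' `corr_threshold`; values of 0.5 or more are conventionally deemed
#' interpretable.
#'
#' @param x A [daily_feature_matrix()] or numeric series matrix.
#' @param config A [fit_config()] used for every refit.
#' @param n_boot Bootstraps per drop proportion (default 1000).
#' @param drop_proportions Grid of drop proportions (max 0.75).
#' @param corr_threshold Correlation retained (default 0.7).
#' @param quantile Coverage requirement (default 0.95).
#' @param seed Integer seed.
#' @param min_rows Smallest subsample refit attempted; smaller draws are
#'   skipped with a log message.
#' @return List of class `stability_result`: `cs_coefficient`,
#'   `drop_proportions`, `q_low` (per-proportion low quantile), `correlations`
#'   (matrix), `interpretable_threshold` (0.5).
#' @export
cs_coefficient <- function(x, config = fit_config(), n_boot = 1000,
                           drop_proportions = seq(0.05, 0.75, by = 0.10),
                           corr_threshold = 0.7, quantile = 0.95,
                           seed = 1L, min_rows = 20L) {
  stopifnot(max(drop_proportions) <= 0.75)
  if (inherits(x, "daily_feature_matrix")) x <- x$values
  x <- as.matrix(x)
  full_fit <- estimate_network(x, config = config)
  full_s <- node_strength(full_fit)
  if (sd(full_s) < 1e-12) {
    message("full-sample network has no strength variation (likely empty); ",
            "CS coefficient set to 0")
    return(structure(list(cs_coefficient = 0,
                          drop_proportions = drop_proportions,
                          q_low = rep(NA_real_, length(drop_proportions)),
                          correlations = matrix(NA_real_, 0,
                                                length(drop_proportions)),
                          corr_threshold = corr_threshold,
                          quantile = quantile,
                          interpretable_threshold = 0.5),
                     class = "stability_result"))
  }
  set.seed(seed)
  n <- nrow(x)
  cors <- matrix(NA_real_, n_boot, length(drop_proportions))
  n_skipped <- 0L
  for (j in seq_along(drop_proportions)) {
    keep_n <- round(n * (1 - drop_proportions[j]))
    for (b in seq_len(n_boot)) {
      if (keep_n < min_rows) { n_skipped <- n_skipped + 1L; next }
      if (keep_n >= n) { cors[b, j] <- 1; next }   # full sample: exact
      rows <- sort(sample.int(n, keep_n))
      fit <- tryCatch(estimate_network(x[rows, , drop = FALSE],
                                       config = config),
                      error = function(e) NULL)
      if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
      cors[b, j] <- safe_cor(node_strength(fit), full_s)
    }
  }
  if (n_skipped > 0)
    message(n_skipped, " bootstrap draw(s) skipped (subsample too small or ",
            "degenerate)")
  q_low <- apply(cors, 2, function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) return(NA_real_)
    unname(stats::quantile(z, 1 - quantile))
  })
  ok <- which(!is.na(q_low) & q_low >= corr_threshold)
  cs <- if (length(ok)) max(drop_proportions[ok]) else 0
  structure(list(cs_coefficient = cs, drop_proportions = drop_proportions,
                 q_low = q_low, correlations = cors,
                 corr_threshold = corr_threshold, quantile = quantile,
                 interpretable_threshold = 0.5),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("CS coefficient: %.2f (threshold r >= %.2f in %.0f%% of draws; ",
              x$cs_coefficient, x$corr_threshold, 100 * x$quantile))
  cat(sprintf("interpretable above %.2f)\n", x$interpretable_threshold))
  invisible(x)
}
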