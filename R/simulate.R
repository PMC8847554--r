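#' Default sparse temporal matrix for the synthetic generator
#'
#' Mild autoregression on the diagonal plus a few weak cross-lagged effects;
#' spectral radius well below 1.
#' @param p Number of nodes.
#' @return p x p matrix.
#' @export
default_temporal <- function(p) {
  B <- diag(0.25, p)
  for (i in seq_len(p - 1)) B[i + 1, i] <- 0.1
  B
}

#' Default innovation precision with known contemporaneous structure
#'
#' Unit diagonal with one strong partial correlation (0.40) and a handful of
#' weak ones (0.10-0.12), mimicking the sparse, weak-edged personalised
#' networks typical of daily language data (one dominant edge, most edges
#' near zero).
#' @param p Number of nodes.
#' @return Symmetric positive-definite p x p matrix.
#' @export
default_precision <- function(p) {
  K <- diag(1, p)
  edge <- function(K, i, j, w) {
    if (p >= max(i, j)) K[i, j] <- K[j, i] <- -w
    K
  }
  K <- edge(K, 1, 2, 0.40)
  K <- edge(K, 3, 4, 0.12)
  K <- edge(K, 5, 6, 0.10)
  K <- edge(K, 7, 8, 0.10)
  K <- edge(K, 2, 9, 0.12)
  stopifnot(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) > 0)
  K
}

#' Dense sparse-truth precision for recovery experiments
#'
#' Eight moderate edges (partial correlations 0.25-0.35) on nine nodes; used
#' as a known truth whose edges are all individually detectable at T = 365.
#' @return Symmetric positive-definite 9 x 9 matrix.
#' @export
recovery_precision <- function() {
  K <- diag(1, 9)
  edges <- list(c(1, 2, 0.35), c(2, 3, 0.28), c(3, 4, 0.25), c(4, 5, 0.30),
                c(5, 6, 0.25), c(6, 7, 0.28), c(7, 8, 0.25), c(1, 9, 0.30))
  for (e in edges) K[e[1], e[2]] <- K[e[2], e[1]] <- -e[3]
  stopifnot(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) > 0)
  K
}

#' Scale the off-diagonals of a precision matrix
#'
#' Multiplying all off-diagonal entries of K by `c` multiplies every partial
#' correlation by `c`; used to raise within-episode connectivity.
#' @param K Symmetric PD matrix.
#' @param multiplier Nonnegative scale factor.
#' @return Scaled matrix (checked to remain positive definite).
#' @export
scale_precision <- function(K, multiplier) {
  stopifnot(multiplier >= 0)
  Ks <- K * multiplier
  diag(Ks) <- diag(K)
  if (min(eigen(Ks, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("scaled within-episode precision is not positive definite")
  Ks
}

#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the cohort structure the pipeline expects: ~1 year
#' of daily word-category percentages per user with missing days, episode
#' schedules (Poisson count with mean `episode_rate`, log-normal durations
#' matching the stated mean/SD), a within-episode connectivity increase
#' obtained by scaling the off-diagonals of the innovation precision, and
#' severity scores linked to both connectivity and feature means.
#'
#' @param n_users Number of users.
#' @param n_days Days in the observation window (default 365).
#' @param n_features Number of word-category features (default 9).
#' @param temporal_matrix Lag-1 coefficient matrix B (spectral radius < 1).
#' @param precision_outside Innovation precision outside episodes (symmetric
#'   positive definite).
#' @param connectivity_multiplier Off-diagonal scale of the precision within
#'   episodes; 1 gives a null cohort.
#' @param episode_rate Mean episodes per user (default 1.56).
#' @param episode_duration_mean_days,episode_duration_sd_days Log-normal
#'   duration parameters on the day scale (defaults 104 and 97).
#' @param missing_day_prob i.i.d. probability a day has no documents.
#' @param user_mean_sd SD of per-user latent mean shifts (drives
#'   between-person feature-mean differences).
#' @param severity_connectivity_slope,severity_feature_slopes,severity_noise_sd
#'   Severity is `slope * standardised mean connectivity + slopes' feature
#'   means + noise`, then z-scored across the cohort; connectivity is
#'   standardised so the slope is in cohort-SD units.
#' @param tokens_per_day Tokens per rendered document (see
#'   [render_documents()]).
#' @param pct_center,pct_scale Latent-to-percentage logistic map:
#'   `100 * plogis((y - pct_center) / pct_scale)`.
#' @param survey_date Survey completion date; day `n_days` of the window.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_users, n_days = 365, n_features = 9,
                             temporal_matrix = default_temporal(n_features),
                             precision_outside = default_precision(n_features),
                             connectivity_multiplier = 1.5,
                             episode_rate = 1.56,
                             episode_duration_mean_days = 104,
                             episode_duration_sd_days = 97,
                             missing_day_prob = 0.2,
                             user_mean_sd = 0.3,
                             severity_connectivity_slope = 1,
                             severity_feature_slopes = rep(0, n_features),
                             severity_noise_sd = 0.5,
                             tokens_per_day = 50,
                             pct_center = 0, pct_scale = 1,
                             survey_date = as.Date("2020-12-31"),
                             seed = 1L) {
  p <- n_features
  B <- as.matrix(temporal_matrix)
  K <- as.matrix(precision_outside)
  stopifnot(nrow(B) == p, ncol(B) == p, nrow(K) == p, ncol(K) == p,
            n_users >= 1, n_days >= 2, missing_day_prob >= 0,
            missing_day_prob < 1, episode_rate >= 0,
            length(severity_feature_slopes) == p)
  if (max(Mod(eigen(B, only.values = TRUE)$values)) >= 1)
    stop("temporal_matrix is non-stationary (spectral radius >= 1)")
  if (!isSymmetric(unname(K), tol = 1e-8))
    stop("precision_outside must be symmetric")
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("precision_outside must be positive definite")
  scale_precision(K, connectivity_multiplier)  # errors if within-K not PD
  structure(list(n_users = as.integer(n_users), n_days = as.integer(n_days),
                 n_features = p, temporal_matrix = B, precision_outside = K,
                 connectivity_multiplier = connectivity_multiplier,
                 episode_rate = episode_rate,
                 episode_duration_mean_days = episode_duration_mean_days,
                 episode_duration_sd_days = episode_duration_sd_days,
                 missing_day_prob = missing_day_prob,
                 user_mean_sd = user_mean_sd,
                 severity_connectivity_slope = severity_connectivity_slope,
                 severity_feature_slopes = severity_feature_slopes,
                 severity_noise_sd = severity_noise_sd,
                 tokens_per_day = as.integer(tokens_per_day),
                 pct_center = pct_center, pct_scale = pct_scale,
                 survey_date = as.Date(survey_date), seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate a stationary lag-1 GVAR series
#'
#' Draws `y_t = B y_{t-1} + e_t` with innovation covariance `solve(precision)`
#' and discards the burn-in.
#'
#' @param temporal_matrix B (spectral radius < 1).
#' @param precision Innovation precision (symmetric PD).
#' @param n_days Length of the returned series.
#' @param burn_in Initial samples discarded (default 200).
#' @param seed Optional integer seed.
#' @return `n_days` x p matrix.
#' @export
simulate_gvar_series <- function(temporal_matrix, precision, n_days,
                                 burn_in = 200, seed = NULL) {
  B <- as.matrix(temporal_matrix)
  K <- as.matrix(precision)
  p <- nrow(B)
  if (max(Mod(eigen(B, only.values = TRUE)$values)) >= 1)
    stop("temporal matrix is non-stationary (spectral radius >= 1)")
  if (!isSymmetric(unname(K), tol = 1e-8) ||
      min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("precision must be symmetric positive definite")
  if (!is.null(seed)) set.seed(seed)
  L <- t(chol(solve(K)))               # innovation covariance factor
  total <- n_days + burn_in
  eps <- L %*% matrix(rnorm(p * total), p, total)
  y <- matrix(0, total, p)
  y[1, ] <- eps[, 1]
  for (t in 2:total) y[t, ] <- B %*% y[t - 1, ] + eps[, t]
  y[(burn_in + 1):total, , drop = FALSE]
}

# log-normal (meanlog, sdlog) matching a target mean and sd on the day scale
lognormal_params <- function(mean_days, sd_days) {
  cv2 <- (sd_days / mean_days)^2
  sdlog <- sqrt(log(1 + cv2))
  list(meanlog = log(mean_days) - sdlog^2 / 2, sdlog = sdlog)
}

# Draw one user's raw episode intervals on the day index scale [1, n_days]
draw_episode_schedule <- function(rate, dur, n_days) {
  k <- min(rpois(1, rate), 5L)
  if (k == 0) return(data.frame(start = integer(0), end = integer(0)))
  durations <- pmax(1, round(rlnorm(k, dur$meanlog, dur$sdlog)))
  starts <- sample.int(n_days, k, replace = TRUE)
  ends <- starts + durations - 1L
  if (any(ends > n_days)) {
    ends <- pmin(ends, n_days)
    message("episode extended beyond the observation window; truncated")
  }
  data.frame(start = starts, end = ends)
}

mean_abs_offdiag <- function(M) {
  mean(abs(M[upper.tri(M)]))
}

#' Simulate a synthetic cohort with known network ground truth
#'
#' Each user receives an episode schedule, a latent GVAR series whose
#' innovation precision switches to the multiplier-scaled matrix on episode
#' days, a daily feature matrix on the percentage scale with missing days
#' dropped, and a severity score tied to mean connectivity and feature means.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_cohort` with `users` (per-user records),
#'   `severity` (user-level table with raw two-scale scores and the latent
#'   z-score), `config`, and `truth` (generating matrices and per-regime mean
#'   absolute partial correlations).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  p <- config$n_features
  n_days <- config$n_days
  B <- config$temporal_matrix
  K_out <- config$precision_outside
  K_in <- scale_precision(K_out, config$connectivity_multiplier)
  L_out <- t(chol(solve(K_out)))
  L_in <- t(chol(solve(K_in)))
  dur <- lognormal_params(config$episode_duration_mean_days,
                          config$episode_duration_sd_days)
  dates <- seq(config$survey_date - n_days + 1, config$survey_date, by = "day")
  feat_names <- paste0("f", seq_len(p))

  conn_out <- mean_abs_offdiag(pcc_from_precision(K_out))
  conn_in <- mean_abs_offdiag(pcc_from_precision(K_in))
  burn_in <- 200L

  users <- vector("list", config$n_users)
  for (u in seq_len(config$n_users)) {
    uid <- sprintf("u%04d", u)
    raw_sched <- draw_episode_schedule(config$episode_rate, dur, n_days)
    within <- rep(FALSE, n_days)
    for (r in seq_len(nrow(raw_sched)))
      within[raw_sched$start[r]:raw_sched$end[r]] <- TRUE
    cal <- if (nrow(raw_sched)) {
      recode_episodes(data.frame(start = dates[raw_sched$start],
                                 end = dates[raw_sched$end]), user_id = uid)
    } else episode_calendar(uid)
    # recoding can merge or drop; re-derive day labels from the calendar
    within <- label_days_logical(cal, dates)

    mu_u <- rnorm(p, 0, config$user_mean_sd)
    eps <- matrix(rnorm(p * (n_days + burn_in)), p)
    reg_in <- c(rep(FALSE, burn_in), within)
    y <- matrix(0, n_days + burn_in, p)
    y[1, ] <- L_out %*% eps[, 1]
    for (t in 2:(n_days + burn_in)) {
      L <- if (reg_in[t]) L_in else L_out
      y[t, ] <- B %*% y[t - 1, ] + L %*% eps[, t]
    }
    y <- y[(burn_in + 1):(n_days + burn_in), , drop = FALSE]
    y <- sweep(y, 2, mu_u, "+")
    colnames(y) <- feat_names

    pct <- 100 * plogis((y - config$pct_center) / config$pct_scale)
    observed <- runif(n_days) >= config$missing_day_prob
    fm <- daily_feature_matrix(
      user_id = uid, dates = dates[observed],
      values = pct[observed, , drop = FALSE],
      word_count = rep(config$tokens_per_day, sum(observed)),
      survey_date = config$survey_date)

    n_in <- sum(within)
    conn_u <- (n_in * conn_in + (n_days - n_in) * conn_out) / n_days

    users[[u]] <- list(user_id = uid, latent = y, features = fm,
                       episodes = cal, episode_days = within,
                       n_days_within = n_in, conn_mean = conn_u,
                       feature_means = colMeans(pct))
  }

  # severity: standardised-connectivity weight + feature-mean slopes + noise
  conn <- vapply(users, `[[`, numeric(1), "conn_mean")
  conn_z <- if (sd(conn) > 1e-12) as.numeric(scale(conn)) else rep(0, length(conn))
  fmeans <- do.call(rbind, lapply(users, `[[`, "feature_means"))
  sev_lat <- config$severity_connectivity_slope * conn_z +
    as.numeric(fmeans %*% config$severity_feature_slopes) +
    rnorm(length(users), 0, config$severity_noise_sd)
  for (u in seq_along(users)) users[[u]]$severity_raw <- sev_lat[u]
  sev_z <- if (sd(sev_lat) > 1e-12) as.numeric(scale(sev_lat)) else
    rep(0, length(sev_lat))
  scale_id <- rep(c("cesd", "sds"), length.out = length(users))
  raw_score <- ifelse(scale_id == "cesd", 8 + 4 * sev_lat, 50 + 10 * sev_lat)
  severity <- data.frame(
    user_id = vapply(users, `[[`, character(1), "user_id"),
    scale = scale_id, score = raw_score, severity_z = sev_z,
    stringsAsFactors = FALSE)

  structure(list(users = users, severity = severity, config = config,
                 truth = list(temporal_matrix = B, precision_outside = K_out,
                              precision_within = K_in,
                              omega_outside = pcc_from_precision(K_out),
                              omega_within = pcc_from_precision(K_in),
                              conn_outside = conn_out, conn_within = conn_in)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n_ep <- sum(vapply(x$users, function(u) nrow(u$episodes$intervals) > 0,
                     logical(1)))
  cat("Synthetic cohort:", length(x$users), "users,",
      x$config$n_days, "days,", x$config$n_features, "features;",
      n_ep, "users with recoded episodes\n")
  invisible(x)
}

#' Render token streams from a latent series through a dictionary
#'
#' Maps each latent value to a category probability with a scaled logistic,
#' assigns the remaining probability to out-of-dictionary filler tokens, and
#' draws `tokens_per_day` tokens i.i.d. per day (uniform word choice within a
#' category). Lets the text module be exercised end-to-end against known
#' generating probabilities.
#'
#' @param series T x p latent matrix (columns must align with the dictionary
#'   category order).
#' @param dictionary A [category_dictionary()].
#' @param tokens_per_day Tokens per day; 0 emits no document for that day.
#' @param seed Optional integer seed.
#' @param dates Optional per-day dates (default consecutive days ending
#'   today).
#' @param prob_scale Scale applied to the logistic output; default `1/p` so
#'   daily category probabilities always sum below 1.
#' @param center,scale Logistic location/scale on the latent axis.
#' @return `data.frame(date, text)` with one row per emitted day.
#' @export
render_documents <- function(series, dictionary, tokens_per_day, seed = NULL,
                             dates = NULL, prob_scale = NULL,
                             center = 0, scale = 1) {
  stopifnot(inherits(dictionary, "category_dictionary"))
  series <- as.matrix(series)
  n_cat <- nrow(dictionary$categories)
  if (ncol(series) != n_cat)
    stop("series has ", ncol(series), " columns but dictionary has ",
         n_cat, " categories")
  if (is.null(prob_scale)) prob_scale <- 1 / n_cat
  if (is.null(dates))
    dates <- seq(Sys.Date() - nrow(series) + 1, Sys.Date(), by = "day")
  if (!is.null(seed)) set.seed(seed)

  cat_words <- category_wordlists(dictionary)
  empty <- vapply(cat_words, length, integer(1)) == 0
  if (any(empty))
    message("empty dictionary categor",
            if (sum(empty) > 1) "ies" else "y", " ",
            paste(dictionary$categories$name[empty], collapse = ", "),
            "; probability reassigned to filler tokens")
  filler <- paste0("zq", seq_len(40))   # never matches dictionary entries

  if (tokens_per_day == 0)
    return(data.frame(date = as.Date(character(0)), text = character(0),
                      stringsAsFactors = FALSE))

  out_date <- as.Date(character(0))
  out_text <- character(0)
  for (t in seq_len(nrow(series))) {
    probs <- prob_scale * plogis((series[t, ] - center) / scale)
    probs[empty] <- 0
    total <- sum(probs)
    if (total > 1) probs <- probs / total
    mix <- c(probs, max(0, 1 - sum(probs)))
    counts <- as.integer(stats::rmultinom(1, tokens_per_day, mix))
    toks <- character(0)
    for (ci in seq_len(n_cat)) {
      if (counts[ci] > 0)
        toks <- c(toks, sample(cat_words[[ci]], counts[ci], replace = TRUE))
    }
    if (counts[n_cat + 1] > 0)
      toks <- c(toks, sample(filler, counts[n_cat + 1], replace = TRUE))
    out_date <- c(out_date, dates[t])
    out_text <- c(out_text, paste(sample(toks), collapse = " "))
  }
  data.frame(date = out_date, text = out_text, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `features.csv` (long format), `episodes.csv`, `severity.csv` and
#' `truth.json`; with `render = TRUE` also `documents.jsonl`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param render Also render token streams through `dictionary`.
#' @param dictionary Dictionary used when `render = TRUE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, render = FALSE, dictionary = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feats <- do.call(rbind, lapply(cohort$users, function(u) {
    fm <- u$features
    if (nrow(fm$values) == 0) return(NULL)
    data.frame(user_id = u$user_id,
               date = rep(as.character(fm$dates), ncol(fm$values)),
               feature = rep(colnames(fm$values), each = nrow(fm$values)),
               value = as.vector(fm$values),
               word_count = rep(fm$word_count, ncol(fm$values)),
               stringsAsFactors = FALSE)
  }))
  write.csv(feats, file.path(dir, "features.csv"), row.names = FALSE)
  eps <- do.call(rbind, lapply(cohort$users, function(u) {
    iv <- u$episodes$intervals
    if (nrow(iv) == 0) return(NULL)
    data.frame(user_id = u$user_id, start_date = as.character(iv$start),
               end_date = as.character(iv$end), stringsAsFactors = FALSE)
  }))
  if (is.null(eps))
    eps <- data.frame(user_id = character(0), start_date = character(0),
                      end_date = character(0))
  write.csv(eps, file.path(dir, "episodes.csv"), row.names = FALSE)
  write.csv(cohort$severity, file.path(dir, "severity.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(temporal_matrix = cohort$truth$temporal_matrix,
         precision_outside = cohort$truth$precision_outside,
         precision_within = cohort$truth$precision_within,
         connectivity_multiplier = cohort$config$connectivity_multiplier,
         seed = cohort$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (render) {
    stopifnot(!is.null(dictionary))
    con <- file(file.path(dir, "documents.jsonl"), "w")
    on.exit(close(con))
    for (u in cohort$users) {
      docs <- render_documents(u$latent, dictionary,
                               cohort$config$tokens_per_day,
                               dates = seq(cohort$config$survey_date -
                                             cohort$config$n_days + 1,
                                           cohort$config$survey_date,
                                           by = "day"))
      for (i in seq_len(nrow(docs)))
        writeLines(jsonlite::toJSON(list(user_id = u$user_id,
                                         date = as.character(docs$date[i]),
                                         text = docs$text[i]),
                                    auto_unbox = TRUE), con)
    }
  }
  invisible(dir)
}
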