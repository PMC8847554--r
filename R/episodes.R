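#' Construct a recoded episode calendar
#'
#' Closed date intervals of self-reported depressive episodes after recoding.
#' A valid calendar has sorted, non-overlapping intervals, each at least 14
#' days long, separated by at least 14 intervening days.
#'
#' @param user_id User identifier.
#' @param intervals `data.frame` with `Date` columns `start`, `end` (may be
#'   empty).
#' @param validate Check the calendar invariants (default `TRUE`).
#' @return An object of class `episode_calendar`.
#' @export
episode_calendar <- function(user_id = NA_character_,
                             intervals = data.frame(start = as.Date(character(0)),
                                                    end = as.Date(character(0))),
                             validate = TRUE) {
  intervals$start <- as.Date(intervals$start)
  intervals$end <- as.Date(intervals$end)
  if (validate && nrow(intervals)) {
    if (any(intervals$start > intervals$end))
      stop("interval with start after end")
    if (is.unsorted(as.integer(intervals$start), strictly = TRUE) &&
        nrow(intervals) > 1)
      stop("intervals must be sorted by start date")
    len <- as.integer(intervals$end - intervals$start) + 1L
    if (any(len < 14L)) stop("interval shorter than 14 days")
    if (nrow(intervals) > 1) {
      gaps <- as.integer(intervals$start[-1] - intervals$end[-nrow(intervals)]) - 1L
      if (any(gaps < 14L)) stop("intervals separated by fewer than 14 days")
    }
  }
  structure(list(user_id = user_id, intervals = intervals),
            class = "episode_calendar")
}

#' @export
print.episode_calendar <- function(x, ...) {
  cat("Episode calendar for", x$user_id, "-", nrow(x$intervals),
      "interval(s)\n")
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

#' Recode raw self-reported episode intervals
#'
#' Raw reports are first unioned where they overlap or touch, then merged when
#' separated by 13 or fewer intervening days (those days become depressed),
#' and finally any residual interval shorter than 14 days is recoded to "not
#' depressed" (removed). Day counting is inclusive: length = end - start + 1.
#'
#' @param raw_intervals `data.frame` with `start`, `end` (coercible to
#'   `Date`); overlaps allowed.
#' @param user_id User identifier carried into the result.
#' @param order `"merge_first"` (default) merges before dropping short
#'   residuals; `"drop_first"` reverses the two steps.
#' @param max_episodes Maximum number of raw reports accepted (default 5,
#'   matching an intake form that accepts up to five); extras are dropped
#'   with a warning.
#' @return An [episode_calendar()].
#' @export
recode_episodes <- function(raw_intervals, user_id = NA_character_,
                            order = c("merge_first", "drop_first"),
                            max_episodes = 5L) {
  order <- match.arg(order)
  iv <- data.frame(start = as.Date(raw_intervals$start),
                   end = as.Date(raw_intervals$end))
  bad <- which(iv$start > iv$end)
  if (length(bad))
    stop("interval ", bad[1], " has start (", iv$start[bad[1]],
         ") after end (", iv$end[bad[1]], ")")
  if (nrow(iv) > max_episodes) {
    warning("more than ", max_episodes, " episodes reported; extra ",
            nrow(iv) - max_episodes, " dropped")
    iv <- iv[seq_len(max_episodes), , drop = FALSE]
  }
  merge_step <- function(iv) {
    if (nrow(iv) < 2) return(iv)
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    out <- iv[1, , drop = FALSE]
    for (r in 2:nrow(iv)) {
      last <- nrow(out)
      # merge when the gap (days strictly between) is <= 13, i.e. the next
      # start is within end + 14; overlaps and adjacency are covered too
      if (as.integer(iv$start[r] - out$end[last]) <= 14L) {
        out$end[last] <- max(out$end[last], iv$end[r])
      } else {
        out <- rbind(out, iv[r, , drop = FALSE])
      }
    }
    out
  }
  drop_step <- function(iv) {
    iv[as.integer(iv$end - iv$start) + 1L >= 14L, , drop = FALSE]
  }
  iv <- if (order == "merge_first") drop_step(merge_step(iv)) else
    merge_step(drop_step(iv))
  rownames(iv) <- NULL
  episode_calendar(user_id = user_id, intervals = iv)
}

# internal: logical within-episode indicator for a date vector
label_days_logical <- function(calendar, dates) {
  dates <- as.Date(dates)
  within <- rep(FALSE, length(dates))
  iv <- calendar$intervals
  for (r in seq_len(nrow(iv)))
    within <- within | (dates >= iv$start[r] & dates <= iv$end[r])
  within
}

#' Label the days of a feature matrix as within or outside episodes
#'
#' A day is `"within"` iff it falls inside any calendar interval (closed
#' intervals: boundary days count as within).
#'
#' @param calendar An [episode_calendar()].
#' @param matrix A [daily_feature_matrix()] (or a `Date` vector).
#' @return Character vector (`"within"`/`"outside"`), one per day.
#' @export
label_days <- function(calendar, matrix) {
  dates <- if (inherits(matrix, "daily_feature_matrix")) matrix$dates else
    as.Date(matrix)
  if (inherits(matrix, "daily_feature_matrix") &&
      !is.na(calendar$user_id) && !is.na(matrix$user_id) &&
      calendar$user_id != matrix$user_id)
    stop("calendar user (", calendar$user_id, ") does not match matrix user (",
         matrix$user_id, ")")
  ifelse(label_days_logical(calendar, dates), "within", "outside")
}

#' Eligibility of a user's daily series for analysis
#'
#' Overall mode requires at least 30 observed days; paired mode requires at
#' least 15 days both within and outside an episode.
#'
#' @param matrix A [daily_feature_matrix()] (or a row count for overall mode).
#' @param labels Day labels from [label_days()] (paired mode).
#' @param mode `"overall"` or `"paired"`.
#' @param min_days,min_paired_days Thresholds (defaults 30 and 15).
#' @return List with `eligible`, `n_total`, `n_within`, `n_outside`.
#' @export
check_eligibility <- function(matrix, labels = NULL,
                              mode = c("overall", "paired"),
                              min_days = 30L, min_paired_days = 15L) {
  mode <- match.arg(mode)
  n_total <- if (inherits(matrix, "daily_feature_matrix"))
    nrow(matrix$values) else as.integer(matrix)
  if (mode == "overall")
    return(list(eligible = n_total >= min_days, n_total = n_total,
                n_within = NA_integer_, n_outside = NA_integer_))
  stopifnot(!is.null(labels), length(labels) == n_total)
  n_within <- sum(labels == "within")
  n_outside <- sum(labels == "outside")
  list(eligible = n_within >= min_paired_days && n_outside >= min_paired_days,
       n_total = n_total, n_within = n_within, n_outside = n_outside)
}

#' Read raw episode intervals from CSV
#'
#' Expects columns `user_id`, `start_date`, `end_date` (ISO-8601).
#'
#' @param path CSV file.
#' @return `data.frame` with `user_id`, `start`, `end` (`Date`).
#' @export
read_episodes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("user_id", "start_date", "end_date") %in% names(df)))
  data.frame(user_id = df$user_id, start = as.Date(df$start_date),
             end = as.Date(df$end_date), stringsAsFactors = FALSE)
}
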