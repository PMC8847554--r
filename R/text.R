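#' Construct a word-category dictionary
#'
#' A LIWC-style lexicon: ordered categories plus entries that are either
#' literal words or stems (trailing `*`), each mapped to one or more
#' category ids.
#'
#' @param categories `data.frame` with integer `id` and character `name`.
#' @param entries `data.frame` with character `pattern` and list-column (or
#'   comma-separated character) `ids`.
#' @return Object of class `category_dictionary`.
#' @export
category_dictionary <- function(categories, entries) {
  categories$id <- as.integer(categories$id)
  if (anyDuplicated(categories$id)) stop("duplicate category id")
  if (anyDuplicated(categories$name)) stop("duplicate category name")
  if (!is.list(entries$ids))
    entries$ids <- lapply(strsplit(as.character(entries$ids), ","),
                          as.integer)
  known <- categories$id
  for (i in seq_len(nrow(entries))) {
    unknown <- setdiff(entries$ids[[i]], known)
    if (length(unknown))
      stop("entry '", entries$pattern[i], "' references unknown category id ",
           paste(unknown, collapse = ", "))
  }
  structure(list(categories = categories, entries = entries),
            class = "category_dictionary")
}

#' @export
print.category_dictionary <- function(x, ...) {
  cat("Category dictionary:", nrow(x$categories), "categories,",
      nrow(x$entries), "entries\n")
  invisible(x)
}

#' Read a `%`-delimited dictionary file
#'
#' Format: a line `%`, then `id<TAB>name` category lines, then `%`, then
#' `pattern<TAB>id[<TAB>id...]` entry lines. A trailing `*` on a pattern
#' marks a stem.
#'
#' @param path Dictionary file.
#' @return A [category_dictionary()].
#' @export
load_dictionary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  seps <- which(lines == "%")
  if (length(seps) < 2) stop("malformed dictionary: need two '%' separator lines")
  cat_lines <- lines[(seps[1] + 1):(seps[2] - 1)]
  cat_lines <- cat_lines[nzchar(cat_lines)]
  parts <- strsplit(cat_lines, "\t")
  categories <- data.frame(
    id = vapply(parts, function(z) as.integer(z[1]), integer(1)),
    name = vapply(parts, function(z) z[2], character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(categories$id))
    stop("duplicate category id in header")
  entry_lines <- lines[(seps[2] + 1):length(lines)]
  keep <- nzchar(entry_lines)
  entry_nums <- ((seps[2] + 1):length(lines))[keep]
  entry_lines <- entry_lines[keep]
  parts <- strsplit(entry_lines, "\t")
  entries <- data.frame(
    pattern = tolower(vapply(parts, function(z) z[1], character(1))),
    stringsAsFactors = FALSE)
  entries$ids <- lapply(parts, function(z) as.integer(z[-1]))
  known <- categories$id
  for (i in seq_along(entries$ids)) {
    unknown <- setdiff(entries$ids[[i]], known)
    if (length(unknown))
      stop("line ", entry_nums[i], ": entry '", entries$pattern[i],
           "' references unknown category id ",
           paste(unknown, collapse = ", "))
  }
  category_dictionary(categories, entries)
}

#' Write a dictionary in the `%`-delimited format
#' @param dictionary A [category_dictionary()].
#' @param path Output file.
#' @export
write_dictionary <- function(dictionary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%", con)
  writeLines(paste(dictionary$categories$id, dictionary$categories$name,
                   sep = "\t"), con)
  writeLines("%", con)
  writeLines(vapply(seq_len(nrow(dictionary$entries)), function(i)
    paste(c(dictionary$entries$pattern[i],
            dictionary$entries$ids[[i]]), collapse = "\t"),
    character(1)), con)
  invisible(path)
}

# internal: literal word per entry, grouped by category (stems lose the `*`)
category_wordlists <- function(dictionary) {
  words <- sub("\\*$", "", dictionary$entries$pattern)
  out <- lapply(dictionary$categories$id, function(id) {
    words[vapply(dictionary$entries$ids, function(z) id %in% z, logical(1))]
  })
  names(out) <- dictionary$categories$name
  out
}

#' Clean a raw document into tokens
#'
#' Removes URLs and @-mentions whole, strips the `#` symbol (keeping the
#' word), drops emojis and all other non-alphanumeric characters except `.`,
#' `!` and `?`, which are kept as separate tokens. Output is lowercased.
#'
#' @param raw_text Character scalar.
#' @param keep_hashtag_word Keep the word following `#` (default) or drop the
#'   whole hashtag.
#' @param drop_mentions Remove `@mention` handles whole (default) or keep the
#'   word.
#' @return Character vector of tokens (possibly empty).
#' @export
clean_text <- function(raw_text, keep_hashtag_word = TRUE,
                       drop_mentions = TRUE) {
  if (is.na(raw_text) || !nzchar(raw_text)) return(character(0))
  x <- raw_text
  x <- gsub("https?://\\S+|www\\.\\S+", " ", x, perl = TRUE)
  x <- if (drop_mentions) gsub("@\\S*", " ", x, perl = TRUE) else
    gsub("@", " ", x, fixed = TRUE)
  x <- if (keep_hashtag_word) gsub("#", "", x, fixed = TRUE) else
    gsub("#\\S*", " ", x, perl = TRUE)
  x <- gsub("([.!?])", " \\1 ", x, perl = TRUE)   # retained punctuation
  x <- gsub("[^[:alnum:].!?[:space:]]", " ", x, perl = TRUE)
  x <- tolower(x)
  toks <- strsplit(trimws(gsub("[[:space:]]+", " ", x)), " ")[[1]]
  toks[nzchar(toks)]
}

#' Score tokens against a dictionary
#'
#' Percentage for a category is `100 * matched / word_count`, where the word
#' count excludes retained punctuation tokens. A token may count toward
#' several categories. Exact-word entries shadow stem entries for the same
#' token by default.
#'
#' @param tokens Token vector from [clean_text()].
#' @param dictionary A [category_dictionary()].
#' @param stem_policy `"shadow"` (exact entries take precedence) or
#'   `"union"`.
#' @return List with `percent` (named numeric per category) and `word_count`;
#'   `NULL` when the word count is zero.
#' @export
score_tokens <- function(tokens, dictionary,
                         stem_policy = c("shadow", "union")) {
  stem_policy <- match.arg(stem_policy)
  words <- tokens[!tokens %in% c(".", "!", "?")]
  wc <- length(words)
  if (wc == 0) return(NULL)
  is_stem <- grepl("\\*$", dictionary$entries$pattern)
  exact_pat <- dictionary$entries$pattern[!is_stem]
  exact_ids <- dictionary$entries$ids[!is_stem]
  stem_pat <- sub("\\*$", "", dictionary$entries$pattern[is_stem])
  stem_ids <- dictionary$entries$ids[is_stem]

  cat_ids <- dictionary$categories$id
  counts <- setNames(numeric(length(cat_ids)), as.character(cat_ids))
  tab <- table(words)
  for (w in names(tab)) {
    hits <- integer(0)
    ex <- which(exact_pat == w)
    if (length(ex)) hits <- unlist(exact_ids[ex])
    if (length(ex) == 0 || stem_policy == "union") {
      st <- which(startsWith(w, stem_pat))
      if (length(st)) hits <- c(hits, unlist(stem_ids[st]))
    }
    hits <- unique(hits)
    if (length(hits))
      counts[as.character(hits)] <- counts[as.character(hits)] + tab[[w]]
  }
  percent <- 100 * counts / wc
  names(percent) <- dictionary$categories$name
  list(percent = percent, word_count = wc)
}

#' Construct a per-user daily feature matrix
#'
#' @param user_id User identifier.
#' @param dates Strictly increasing `Date` vector (days with documents).
#' @param values days x features matrix of percentages in \[0, 100\].
#' @param word_count Integer vector of words per day.
#' @param survey_date Survey completion date (no day may fall after it).
#' @return Object of class `daily_feature_matrix`.
#' @export
daily_feature_matrix <- function(user_id, dates, values, word_count,
                                 survey_date) {
  dates <- as.Date(dates)
  values <- as.matrix(values)
  stopifnot(length(dates) == nrow(values),
            length(word_count) == nrow(values))
  if (length(dates) > 1 && is.unsorted(as.integer(dates), strictly = TRUE))
    stop("dates must be strictly increasing")
  if (nrow(values) && (min(values) < 0 || max(values) > 100))
    stop("feature values must lie in [0, 100]")
  survey_date <- as.Date(survey_date)
  if (length(dates) && max(dates) > survey_date)
    stop("days after the survey date are not allowed")
  structure(list(user_id = user_id, dates = dates, values = values,
                 word_count = as.integer(word_count),
                 survey_date = survey_date),
            class = "daily_feature_matrix")
}

#' @export
print.daily_feature_matrix <- function(x, ...) {
  cat("Daily feature matrix for", x$user_id, "-", nrow(x$values), "days x",
      ncol(x$values), "features (survey", as.character(x$survey_date), ")\n")
  invisible(x)
}

#' Aggregate documents into per-user daily feature matrices
#'
#' All documents of one user-day are concatenated before scoring (daily
#' bins); days outside the 12 months preceding the survey date are dropped;
#' days whose cleaned text has zero words are skipped.
#'
#' @param documents `data.frame` with columns `user_id` (optional for a
#'   single user), `date` (or `timestamp`), `text`; rows may be unordered.
#' @param dictionary A [category_dictionary()].
#' @param survey_date Survey completion date, or a `data.frame`
#'   (`user_id`, `survey_date`) for per-user dates.
#' @param window_days Length of the analysis window (default 365).
#' @return A [daily_feature_matrix()] for a single user, or a named list of
#'   them for several; users with no in-window scored days yield an empty
#'   matrix with a message.
#' @export
build_daily_matrix <- function(documents, dictionary, survey_date,
                               window_days = 365L) {
  df <- as.data.frame(documents, stringsAsFactors = FALSE)
  if (!"date" %in% names(df)) {
    stopifnot("timestamp" %in% names(df))
    df$date <- as.Date(substr(as.character(df$timestamp), 1, 10))
  }
  df$date <- as.Date(df$date)
  if (!"user_id" %in% names(df)) df$user_id <- "user"
  sd_map <- if (is.data.frame(survey_date))
    setNames(as.Date(survey_date$survey_date), survey_date$user_id) else NULL

  one_user <- function(sub, uid) {
    sdate <- if (is.null(sd_map)) as.Date(survey_date) else sd_map[[uid]]
    inwin <- sub$date > sdate - window_days & sub$date <= sdate
    sub <- sub[inwin, , drop = FALSE]
    feats <- character(0); wcs <- integer(0); days <- as.Date(character(0))
    rows <- list()
    for (d in sort(unique(sub$date))) {
      txt <- paste(sub$text[sub$date == d], collapse = " ")
      sc <- score_tokens(clean_text(txt), dictionary)
      if (is.null(sc)) next
      rows[[length(rows) + 1L]] <- sc$percent
      wcs <- c(wcs, sc$word_count)
      days <- c(days, as.Date(d, origin = "1970-01-01"))
    }
    if (!length(rows)) {
      message("user ", uid, " has no scorable in-window days")
      vals <- matrix(numeric(0), 0, nrow(dictionary$categories),
                     dimnames = list(NULL, dictionary$categories$name))
      return(daily_feature_matrix(uid, as.Date(character(0)), vals,
                                  integer(0), sdate))
    }
    vals <- do.call(rbind, rows)
    rownames(vals) <- NULL
    daily_feature_matrix(uid, days, vals, wcs, sdate)
  }

  uids <- unique(df$user_id)
  out <- lapply(uids, function(u) one_user(df[df$user_id == u, , drop = FALSE], u))
  names(out) <- uids
  if (length(out) == 1) out[[1]] else out
}

#' Read a long-format features CSV into daily feature matrices
#'
#' Expects columns `user_id`, `date`, `feature`, `value` and optionally
#' `word_count`.
#'
#' @param path CSV file.
#' @param survey_date Survey date applied to every user.
#' @return Named list of [daily_feature_matrix()] objects.
#' @export
read_features <- function(path, survey_date) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("user_id", "date", "feature", "value") %in% names(df)))
  df$date <- as.Date(df$date)
  feats <- unique(df$feature)
  out <- lapply(split(df, df$user_id), function(sub) {
    days <- sort(unique(sub$date))
    vals <- matrix(NA_real_, length(days), length(feats),
                   dimnames = list(NULL, feats))
    idx <- cbind(match(sub$date, days), match(sub$feature, feats))
    vals[idx] <- sub$value
    wc <- if ("word_count" %in% names(sub))
      sub$word_count[match(days, sub$date)] else rep(NA_integer_, length(days))
    daily_feature_matrix(sub$user_id[1], days, vals, wc,
                         as.Date(survey_date))
  })
  out
}
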