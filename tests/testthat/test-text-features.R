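test_that("clean_text applies the cleaning rules", {
  expect_equal(clean_text("@jo I won! #happy http://t.co/x"),
               c("i", "won", "!", "happy"))
  expect_equal(clean_text(""), character(0))
  expect_equal(clean_text("a…b\U0001F642c"), c("a", "b", "c"))
  expect_equal(clean_text("Wait... what?!"),
               c("wait", ".", ".", ".", "what", "?", "!"))
  # configurable hashtag/mention handling
  expect_equal(clean_text("#happy days", keep_hashtag_word = FALSE), "days")
  expect_equal(clean_text("@jo hi", drop_mentions = FALSE), c("jo", "hi"))
})

test_that("dictionary parsing round-trips and rejects malformed input", {
  d <- toy_dict()
  expect_s3_class(d, "category_dictionary")
  expect_equal(nrow(d$categories), 9)
  path <- withr::local_tempfile(fileext = ".dic")
  write_dictionary(d, path)
  d2 <- load_dictionary(path)
  expect_equal(d2$categories, d$categories)
  expect_equal(d2$entries$pattern, d$entries$pattern)

  bad <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tone", "2\ttwo", "%", "happ*\t2", "word\t99"), bad)
  expect_error(load_dictionary(bad), "line 6.*unknown category id 99")
  dup <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tone", "1\ttwo", "%", "w\t1"), dup)
  expect_error(load_dictionary(dup), "duplicate")
})

test_that("stem entries match prefixes", {
  d <- toy_dict()
  sc <- score_tokens(c("happy", "happier", "joyful", "table"), d)
  expect_equal(unname(sc$percent["positive_emotion"]), 75)
  expect_equal(sc$word_count, 4)
})

test_that("score_tokens matches the spec examples", {
  d <- mini_dict()
  sc <- score_tokens(c("i", "am", "not", "happy"), d)
  expect_equal(unname(sc$percent["NEGATE"]), 25)
  expect_equal(unname(sc$percent["FIRSTP"]), 25)
  expect_equal(sc$word_count, 4)
  # all out-of-dictionary
  sc0 <- score_tokens(c("table", "chair"), d)
  expect_true(all(sc0$percent == 0))
  # zero word count (only punctuation)
  expect_null(score_tokens(c("!", "."), d))
})

test_that("scoring agrees with a brute-force matcher on random inputs", {
  # dictionary with overlaps: a stem in two categories, exact shadowing a stem
  d <- category_dictionary(
    data.frame(id = 1:3, name = c("A", "B", "C")),
    data.frame(pattern = c("lov*", "love", "lo*", "banana", "nev*"),
               ids = I(list(c(1L, 2L), 3L, 2L, 1L, c(2L, 3L)))))
  vocab <- c("love", "lover", "lox", "lo", "banana", "never", "nevertheless",
             "other", "l")
  set.seed(42)
  for (rep in 1:20) {
    toks <- sample(vocab, sample(3:12, 1), replace = TRUE)
    for (policy in c("shadow", "union")) {
      got <- score_tokens(toks, d, stem_policy = policy)
      expect_equal(got$percent, brute_score(toks, d, policy),
                   info = paste(policy, paste(toks, collapse = " ")))
    }
  }
})

test_that("exact entries shadow stems, union policy adds them", {
  d <- category_dictionary(
    data.frame(id = 1:2, name = c("EXACT", "STEM")),
    data.frame(pattern = c("love", "lov*"), ids = I(list(1L, 2L))))
  shadow <- score_tokens(c("love"), d)
  expect_equal(unname(shadow$percent), c(100, 0))
  union <- score_tokens(c("love"), d, stem_policy = "union")
  expect_equal(unname(union$percent), c(100, 100))
})

test_that("build_daily_matrix aggregates, windows, and orders correctly", {
  d <- mini_dict()
  survey <- as.Date("2021-06-30")
  docs <- data.frame(
    user_id = "u1",
    date = c("2021-06-10", "2021-06-10", "2021-06-12", "2020-05-01"),
    text = c("i am not ok", "never say never again i think",
             "plain words here", "i i i"),
    stringsAsFactors = FALSE)
  m <- build_daily_matrix(docs, d, survey)
  expect_s3_class(m, "daily_feature_matrix")
  expect_equal(nrow(m$values), 2)              # 400-day-old doc excluded
  expect_equal(m$word_count[1], 4 + 6)         # same-day concatenation
  expect_true(!is.unsorted(m$dates, strictly = TRUE))
  # document order within a day is irrelevant
  m2 <- build_daily_matrix(docs[c(2, 1, 3, 4), ], d, survey)
  expect_equal(m$values, m2$values)

  # user with no in-window days yields an empty, flagged matrix
  old <- data.frame(user_id = "u2", date = "2019-01-01", text = "i me")
  expect_message(m0 <- build_daily_matrix(old, d, survey), "no scorable")
  expect_equal(nrow(m0$values), 0)
})

test_that("daily_feature_matrix enforces its invariants", {
  expect_error(daily_feature_matrix("u", as.Date("2021-01-02") + c(0, 0),
                                    matrix(1, 2, 2), c(3, 3),
                                    as.Date("2021-06-30")),
               "strictly increasing")
  expect_error(daily_feature_matrix("u", as.Date("2021-01-02"),
                                    matrix(101, 1, 2), 3,
                                    as.Date("2021-06-30")),
               "0, 100")
  expect_error(daily_feature_matrix("u", as.Date("2021-07-02"),
                                    matrix(1, 1, 2), 3, as.Date("2021-06-30")),
               "after the survey date")
})

test_that("disjoint-category percentages sum to at most 100", {
  d <- toy_dict()   # categories are disjoint by construction
  set.seed(1)
  vocab <- c(sub("\\*$", "", d$entries$pattern), letters)
  for (rep in 1:10) {
    toks <- sample(vocab, 30, replace = TRUE)
    sc <- score_tokens(toks, d)
    expect_lte(sum(sc$percent), 100 + 1e-9)
  }
})
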