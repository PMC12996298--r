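test_that("normalisation lowercases lemmas and drops stop words", {
  tk <- toy_tokens()
  out <- normalize_text(tk)
  expect_true("gefühl" %in% out)       # content lemma kept, lowercased
  expect_false(any(out %in% function_word_inventory()))
  expect_false("." %in% out)
  # all-function-word diary -> empty
  fn <- tk[tk$role == "function", ]
  expect_length(normalize_text(fn), 0)
  # idempotence: re-wrapping the output as a diary changes nothing
  wrapped <- data.frame(surface = out, lemma = out, role = "content",
                        sentence = 1L)
  expect_equal(normalize_text(wrapped), out)
})

test_that("silence detection honours threshold and minimum duration", {
  rate <- 16000
  spec <- silence_spec()
  # pure zeros, 2 s -> one silence covering [0, 2]
  s <- detect_silences(numeric(2 * rate), rate, spec)
  expect_equal(nrow(s), 1)
  expect_equal(s$start_s, 0)
  expect_equal(s$end_s, 2, tolerance = 1e-6)
  # full-scale sine -> no silences
  t <- seq(0, 2, length.out = 2 * rate)
  expect_equal(nrow(detect_silences(sin(2 * pi * 440 * t), rate, spec)), 0)
  # 1 s tone + 0.7 s near-silence + 1 s tone -> exactly one ~0.7 s silence
  tone <- sin(2 * pi * 440 * seq(0, 1, length.out = rate))
  quiet <- 1e-4 * sin(2 * pi * 440 * seq(0, 0.7, length.out = 0.7 * rate))
  sig <- c(tone, quiet, tone)
  s <- detect_silences(sig, rate, spec)
  expect_equal(nrow(s), 1)
  expect_equal(s$end_s - s$start_s, 0.7, tolerance = 0.08)
  # same construction with a 0.3 s gap -> below the minimum, no silence
  quiet3 <- 1e-4 * sin(2 * pi * 440 * seq(0, 0.3, length.out = 0.3 * rate))
  expect_equal(nrow(detect_silences(c(tone, quiet3, tone), rate, spec)), 0)
  expect_equal(nrow(detect_silences(numeric(0), rate, spec)), 0)
})

test_that("silence durations respect the spec and never exceed the signal", {
  rate <- 8000
  withr::with_seed(3, {
    for (i in 1:5) {
      n <- rate * 3
      sig <- rnorm(n, 0, 0.5)
      gaps <- sort(sample(4:8, 2))
      sig[(gaps[1] * rate / 4):(gaps[2] * rate / 4)] <- 0
      s <- detect_silences(sig, rate)
      if (nrow(s)) {
        expect_true(all(s$end_s - s$start_s >= 0.5 - 1e-9))
        expect_lte(sum(s$end_s - s$start_s), n / rate + 1e-9)
        expect_true(all(diff(as.vector(t(as.matrix(s)))) >= -1e-12))
      }
    }
  })
})

test_that("timing/lexical vector has 18 named statistics with exact values", {
  tk <- toy_tokens()
  v <- timing_lexical(tk, duration_s = 60,
                      silences = data.frame(start_s = 5, end_s = 15))
  expect_length(v, 18)
  expect_equal(unname(v["pause_time_s"]), 10)
  expect_equal(unname(v["speech_time_s"]), 50)
  expect_equal(unname(v["token_count"]), 9)
  expect_equal(unname(v["sentence_count"]), 2)
  expect_equal(unname(v["function_word_share"]), 3 / 9)
  expect_equal(unname(v["numeral_count"]), 1)
  expect_equal(unname(v["proper_noun_count"]), 1)
  expect_equal(unname(v["first_person_share"]), 1 / 9)
  # type-token ratio definition
  tk2 <- data.frame(surface = rep(c("a", "b"), c(6, 2)),
                    lemma = rep(c("a", "b"), c(6, 2)),
                    role = "content", sentence = 1L)
  v2 <- timing_lexical(tk2, 10)
  expect_equal(unname(v2["type_token_ratio"]), 2 / 8)
  # empty transcript
  v0 <- timing_lexical(tk[0, ], 60)
  expect_equal(unname(v0["token_count"]), 0)
  expect_equal(unname(v0["speech_time_s"]), 60)
  # zero duration flags rates
  vz <- timing_lexical(tk, 0)
  expect_true(attr(vz, "zero_duration"))
  expect_equal(unname(vz["articulation_rate"]), 0)
})

test_that("timing/lexical statistics are invariant to sentence order", {
  co <- small_cohort(5, seed = 21)
  id <- co$diaries$diary_id[1]
  tk <- diary_tokens(co, id)
  v1 <- timing_lexical(tk, 90, pause_s = 12)
  sents <- unique(tk$sentence)
  tk2 <- do.call(rbind, lapply(rev(sents), function(s) tk[tk$sentence == s, ]))
  v2 <- timing_lexical(tk2, 90, pause_s = 12)
  expect_equal(v1, v2)
})

test_that("tf-idf matches a hand-computed 3-document table", {
  corpus <- list(c("a", "b"), c("a", "c"), c("a"))
  m <- tfidf_fit(corpus, ngram_range = c(1, 1))
  idf <- function(df) log((1 + 3) / (1 + df)) + 1
  expect_equal(m$idf[m$vocabulary == "a"], idf(3))
  expect_equal(m$idf[m$vocabulary == "b"], idf(1))
  x <- tfidf_transform(m, corpus)
  # doc 1: tf = (1,1,0) * idf(a,b,c), L2 normalised
  raw <- c(idf(3), idf(1), 0)
  expect_equal(unname(x[1, c("a", "b", "c")]), raw / sqrt(sum(raw^2)))
  expect_equal(unname(x[3, "a"]), 1) # single-term doc -> unit vector
  # ubiquitous term weighted strictly below a rare term at equal tf
  expect_lt(x[1, "a"], x[1, "b"])
  # rows have unit norm (or zero for empty docs)
  x2 <- tfidf_transform(m, list(c("a", "b", "c"), character()))
  expect_equal(sqrt(rowSums(x2^2)), c(1, 0))
})

test_that("bigram features and transform of unseen terms behave", {
  corpus <- list(c("x", "y", "z"), c("x", "y"))
  m <- tfidf_fit(corpus, ngram_range = c(1, 2))
  expect_true("x y" %in% m$vocabulary)
  # unseen n-grams are ignored at transform time
  x <- tfidf_transform(m, list(c("q", "r")))
  expect_equal(sum(x), 0)
  expect_error(tfidf_fit(list()), "empty")
  # single-document corpus: all idf equal -> direction equals tf direction
  m1 <- tfidf_fit(list(c("a", "a", "b")), ngram_range = c(1, 1))
  x1 <- tfidf_transform(m1, list(c("a", "a", "b")))
  expect_equal(unname(x1[1, "a"] / x1[1, "b"]), 2)
})

test_that("tf-idf model serialises to JSON and back", {
  co <- small_cohort(6, seed = 31)
  corp <- normalized_corpus(co)
  m <- tfidf_fit(corp, max_features = 50)
  path <- withr::local_tempfile(fileext = ".json")
  tfidf_save(m, path)
  m2 <- tfidf_load(path)
  expect_equal(m2$vocabulary, m$vocabulary)
  expect_equal(m2$idf, m$idf)
  expect_equal(tfidf_transform(m2, corp), tfidf_transform(m, corp))
})
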