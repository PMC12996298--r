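test_that("word-order shuffle conserves per-sentence multisets", {
  tk <- toy_tokens()
  out <- perturb_word_order(tk, seed = 3)
  expect_equal(nrow(out), nrow(tk))
  for (s in unique(tk$sentence)) {
    expect_setequal(out$surface[out$sentence == s],
                    tk$surface[tk$sentence == s])
  }
  # one-token sentence unchanged
  one <- tk[3, ]
  expect_equal(perturb_word_order(one, seed = 1)$surface, one$surface)
  # pure function of (tokens, seed)
  expect_identical(perturb_word_order(tk, 9), perturb_word_order(tk, 9))
})

test_that("word-order permutations are uniform over the 6 orders", {
  tk <- data.frame(surface = c("a", "b", "c"), lemma = c("a", "b", "c"),
                   role = "content", sentence = 1L)
  orders <- withr::with_seed(99, {
    vapply(1:600, function(i) {
      paste(perturb_word_order(tk, seed = sample.int(1e6, 1))$surface,
            collapse = "")
    }, character(1))
  })
  tab <- table(orders)
  expect_equal(length(tab), 6)
  # each of the 6 orders within binomial sampling error of 100
  expect_true(all(abs(tab - 100) < 4 * sqrt(600 * (1 / 6) * (5 / 6))))
})

test_that("punctuation stays glued to its preceding token", {
  tk <- toy_tokens() # "." follows "gehabt" in sentence 1
  withr::with_seed(5, {
    for (i in 1:20) {
      out <- perturb_word_order(tk, seed = i)
      s1 <- out[out$sentence == 1, ]
      pos <- which(s1$surface == ".")
      expect_equal(s1$surface[pos - 1], "gehabt")
    }
  })
})

test_that("lemmatisation replaces surfaces except numerals/proper nouns", {
  tk <- toy_tokens()
  out <- perturb_lemmatize(tk)
  expect_equal(out$surface[3], "Gefühl")
  expect_equal(out$surface[tk$role == "numeral"], "2021")
  expect_equal(out$surface[tk$role == "proper_noun"], "Anna")
  # idempotent
  expect_identical(perturb_lemmatize(out), out)
  # missing lemma keeps surface with a warning
  tk$lemma[3] <- NA
  expect_warning(out2 <- perturb_lemmatize(tk), "without lemma")
  expect_equal(out2$surface[3], "Gefühle")
})

test_that("vowel masking replaces exactly the German vowel set", {
  tk <- data.frame(surface = c("Gefühl", "Brr", "Ähre"),
                   lemma = c("Gefühl", "Brr", "Ähre"),
                   role = "content", sentence = 1L)
  out <- perturb_vowel_mask(tk)
  expect_equal(out$surface, c("G_f_hl", "Brr", "_hr_"))
  expect_equal(nchar(out$surface), nchar(tk$surface)) # length preserved
  expect_identical(perturb_vowel_mask(out)$surface, out$surface) # idempotent
})

test_that("intra-word shuffle keeps ends, length boundary and multiset", {
  tk <- data.frame(surface = c("Haus", "abcde", "Wanderung"),
                   lemma = c("Haus", "abcde", "Wanderung"),
                   role = "content", sentence = 1L)
  out <- perturb_intraword_shuffle(tk, seed = 11)
  expect_equal(out$surface[1], "Haus") # length 4 unchanged
  for (i in 2:3) {
    s0 <- tk$surface[i]; s1 <- out$surface[i]
    expect_equal(substr(s1, 1, 1), substr(s0, 1, 1))
    expect_equal(substr(s1, nchar(s1), nchar(s1)),
                 substr(s0, nchar(s0), nchar(s0)))
    expect_setequal(strsplit(s1, "")[[1]], strsplit(s0, "")[[1]])
  }
})

test_that("interior permutations of 'abcde' are uniform over 3!", {
  tk <- data.frame(surface = "abcde", lemma = "abcde", role = "content",
                   sentence = 1L)
  outs <- withr::with_seed(7, {
    vapply(1:600, function(i) {
      perturb_intraword_shuffle(tk, seed = sample.int(1e6, 1))$surface
    }, character(1))
  })
  tab <- table(outs)
  expect_equal(length(tab), 6)
  expect_true(all(abs(tab - 100) < 4 * sqrt(600 * (1 / 6) * (5 / 6))))
})

test_that("skeleton and content-only partition the diary", {
  tk <- toy_tokens()
  sk <- perturb_function_skeleton(tk)
  ct <- perturb_content_only(tk)
  expect_setequal(c(sk$surface, ct$surface), tk$surface)
  expect_equal(nrow(sk) + nrow(ct), nrow(tk))
  expect_true(all(sk$role %in% c("function", "punct")))
  expect_false(any(ct$role %in% c("function", "punct")))
  # all-function diary -> empty content
  fn <- tk[tk$role == "function", ]
  expect_equal(nrow(perturb_content_only(fn)), 0)
  # generator ground truth: skeleton share equals tagged fraction exactly
  co <- small_cohort(5, seed = 41)
  id <- co$diaries$diary_id[2]
  d <- diary_tokens(co, id)
  expect_equal(nrow(perturb_function_skeleton(d)),
               sum(d$role == "function"))
})

test_that("perturb_cohort validates seeds and keeps diary structure", {
  co <- small_cohort(5, seed = 43)
  expect_error(perturb_cohort(co, "word_order"), "seed required")
  p <- perturb_cohort(co, "word_order", seed = 2)
  expect_setequal(unique(p$tokens$diary_id), unique(co$tokens$diary_id))
  expect_equal(nrow(p$tokens), nrow(co$tokens))
  p2 <- perturb_cohort(co, "identity")
  expect_identical(p2$tokens, co$tokens)
})

test_that("identity condition yields exactly zero deltas and p near 1", {
  co <- generate_cohort(cohort_config(n_participants = 25, seed = 47,
                                      adherence_log_mean = log(2),
                                      adherence_log_sd = 0.5,
                                      tokens_per_diary = 30))
  pr <- embedding_provider("t", dim = 32, seed = 3, target_r2 = 0.3)
  st <- run_perturbation_study(co, pr, kinds = "identity",
                               space = search_space(budget = 2),
                               seed = 5, n_perm = 200)
  cmp <- st$comparisons
  expect_equal(cmp$delta_mae, 0)
  expect_equal(cmp$delta_r2, 0)
  expect_equal(cmp$p_mae, 1)
})
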