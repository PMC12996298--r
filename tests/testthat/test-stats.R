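test_that("sign-flip enumeration is exact for canonical cases", {
  # d = (1,1,1,1,1): only the all-plus and all-minus patterns reach |1|
  r <- signflip_test(c(1, 1, 1, 1, 1))
  expect_true(r$exhaustive)
  expect_equal(r$p, 2 / 32)
  # d with mean zero: every pattern ties or exceeds, p = 1
  r2 <- signflip_test(c(1, -1, 1, -1, 0))
  expect_equal(r2$p, 1)
  # symmetry: d and -d give identical p
  d <- c(0.3, 1.2, -0.4, 0.8, 0.9)
  expect_equal(signflip_test(d)$p, signflip_test(-d)$p)
  # all-zero differences degenerate cleanly
  r3 <- signflip_test(rep(0, 5))
  expect_equal(r3$p, 1)
  expect_equal(r3$ci, c(0, 0))
})

test_that("sampled sign-flip mode agrees with enumeration within MC error", {
  d <- c(0.5, 1.1, 0.2, 0.9, 1.4, 0.3, 0.8, 1.0, 0.1, 0.6, 0.7, 1.2, 0.4)
  stopifnot(2^length(d) > 4096) # forces sampling
  exact_p <- {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(d))))
    nm <- abs(as.numeric(signs %*% d) / length(d))
    mean(nm >= abs(mean(d)) - 1e-12)
  }
  r <- signflip_test(d, n_perm = 4000, seed = 9)
  expect_false(r$exhaustive)
  expect_gte(r$p, 1 / 4001) # add-one floor
  expect_lt(abs(r$p - exact_p), 0.01 + 3 * sqrt(exact_p / 4000))
})

test_that("paired fold diffs enforce plan-hash equality", {
  expect_error(paired_fold_diffs("a", "b", "mae", 1:5, "h1", "h2"),
               "fold plans differ")
  fd <- paired_fold_diffs("a", "b", "mae", c(1, 2), "h", "h")
  expect_s3_class(fd, "voicebdi_fold_diffs")
})

test_that("effect sizes match closed forms and flag degeneracies", {
  expect_true(is.infinite(cohen_dz(c(2, 2, 2))$dz))
  d <- c(1, 2, 3)
  expect_equal(cohen_dz(d)$dz, mean(d) / sd(d))
  expect_equal(cliffs_delta(c(1, 2, 3), c(0, 0, 0)), 1)
  expect_equal(cliffs_delta(c(0, 0), c(1, 1)), -1)
  expect_equal(cliffs_delta(c(1, 2), c(1, 2)), 0)
  expect_equal(cohens_f2(0.41, 0.34)$f2, (0.41 - 0.34) / (1 - 0.41))
  expect_equal(cohens_f2(0.41, 0.34)$f2, 0.1186, tolerance = 1e-3)
  expect_true(cohens_f2(1, 0.5)$degenerate)
})

test_that("Holm step-down matches a by-hand example and is monotone", {
  r <- holm_bonferroni(c(1, 1, 1))
  expect_false(any(r$reject))
  r2 <- holm_bonferroni(c(0.01, 0.04), alpha = 0.05)
  expect_true(all(r2$reject)) # 0.01 <= 0.025 then 0.04 <= 0.05
  withr::with_seed(3, {
    p <- runif(21)
    r3 <- holm_bonferroni(p)
    expect_true(all(r3$adjusted >= p))
    expect_true(all(diff(sort(r3$adjusted)) >= 0))
  })
})

test_that("Holm controls FWER at 5% under a 21-item null", {
  withr::with_seed(11, {
    reps <- 2000
    any_rej <- vapply(seq_len(reps), function(i) {
      any(holm_bonferroni(runif(21))$reject)
    }, logical(1))
    fwer <- mean(any_rej)
    expect_lt(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  })
})

test_that("Spearman rho with Fisher-z CI behaves on canonical inputs", {
  r <- spearman_fisher_ci(1:10, (1:10)^2)
  expect_equal(r$rho, 1)
  expect_true(r$degenerate)
  r2 <- spearman_fisher_ci(c(1, 1, 1, 1), 1:4)
  expect_true(r2$undefined)
  # tied-rank fixture checked against the rank-correlation definition
  x <- c(1, 2, 2, 3, 4, 4)
  y <- c(2, 1, 3, 3, 5, 4)
  r3 <- spearman_fisher_ci(x, y)
  expect_equal(r3$rho, cor(rank(x), rank(y)))
  # independent draws: rho near 0, CI covers 0
  withr::with_seed(13, {
    a <- rnorm(1000); b <- rnorm(1000)
    r4 <- spearman_fisher_ci(a, b)
    expect_lt(abs(r4$rho), 0.08)
    expect_lt(r4$ci[1], 0)
    expect_gt(r4$ci[2], 0)
  })
})

test_that("Kruskal-Wallis matches stats::kruskal.test and handles ties", {
  g <- list(c(1, 2, 3), c(10, 11, 12))
  r <- kruskal_wallis(g)
  ref <- kruskal.test(unlist(g), factor(rep(1:2, each = 3)))
  expect_equal(r$H, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5)))$H, 0)
})

test_that("label shuffle test validates inputs and finds planted signal", {
  co <- generate_cohort(cohort_config(n_participants = 40, seed = 51,
                                      adherence_log_mean = log(3),
                                      adherence_log_sd = 0.5,
                                      tokens_per_diary = 20))
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 16, seed = 2, target_r2 = 0.5)
  x <- build_modality_matrix(co, pr, mt$diary_id)
  plan <- build_fold_plan(unique(mt$participant_id), seed = 3)
  expect_error(label_shuffle_test(x, mt$bdi_sum, mt$participant_id, plan,
                                  n_perm = 5), ">= 20")
  r <- label_shuffle_test(x, mt$bdi_sum, mt$participant_id, plan,
                          space = search_space(budget = 0), n_perm = 49,
                          seed = 7)
  expect_lt(r$p, 0.1) # planted signal detected
  expect_gte(r$p, 1 / 50)
})

test_that("participant-level shuffle permutes whole blocks within counts", {
  y <- c(1, 1, 2, 2, 3, 4)
  pid <- c("a", "a", "b", "b", "c", "d")
  withr::with_seed(17, {
    for (i in 1:10) {
      yp <- voicebdi:::permute_targets(y, pid, "participant")
      # blocks stay intact: a's two entries remain equal
      expect_equal(yp[1], yp[2])
      expect_equal(yp[3], yp[4])
      # count-1 participants can swap only with each other
      expect_setequal(yp[5:6], c(3, 4))
      expect_setequal(yp, y)
    }
  })
})

test_that("bootstrap CI covers the mean of a known distribution", {
  withr::with_seed(19, {
    x <- rnorm(400, 5, 2)
    ci <- boot_ci(x, mean, n_boot = 1000, seed = 21)
    expect_lt(ci[1], 5.3)
    expect_gt(ci[2], 4.7)
    expect_lt(ci[2] - ci[1], 1)
  })
})
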