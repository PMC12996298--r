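test_that("fold plans are balanced, disjoint and reproducible", {
  p <- sprintf("P%02d", 1:10)
  plan <- build_fold_plan(p, n_outer = 5, n_inner = 3, seed = 2)
  expect_equal(as.numeric(table(plan$outer)), rep(2, 5))
  for (f in 1:5) {
    tr <- names(plan$inner[[f]])
    te <- names(plan$outer)[plan$outer == f]
    expect_length(intersect(tr, te), 0) # no participant on both sides
  }
  plan2 <- build_fold_plan(p, n_outer = 5, n_inner = 3, seed = 2)
  expect_identical(plan$plan_hash, plan2$plan_hash)
  plan3 <- build_fold_plan(p, n_outer = 5, n_inner = 3, seed = 3)
  expect_false(identical(plan$plan_hash, plan3$plan_hash))
  expect_error(build_fold_plan(p[1:3], n_outer = 5), "fewer participants")
})

test_that("stratified plans put both classes in every fold", {
  p <- sprintf("P%02d", 1:20)
  strata <- rep(c("MDD", "HC"), each = 10)
  plan <- build_fold_plan(p, seed = 4, strata = strata)
  for (f in 1:5) {
    te <- names(plan$outer)[plan$outer == f]
    expect_setequal(unique(strata[match(te, p)]), c("MDD", "HC"))
  }
  expect_error(build_fold_plan(p, seed = 1,
                               strata = c(rep("A", 18), rep("B", 2))),
               "stratum")
})

test_that("every paired diary is predicted exactly once per model", {
  co <- small_cohort(20, seed = 61)
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 16, seed = 5, target_r2 = 0.3)
  x <- build_modality_matrix(co, pr, mt$diary_id)
  plan <- build_fold_plan(unique(mt$participant_id), seed = 6)
  res <- fit_eval_single(x, mt$bdi_sum, mt$participant_id, plan,
                         search_space(budget = 2), "m")
  expect_equal(sort(res$predictions$diary_id), sort(mt$diary_id))
  expect_false(anyNA(res$predictions$y_pred))
  # predictions for a diary come from a model not trained on its speaker
  for (f in 1:5) {
    te_pids <- unique(mt$participant_id[res$predictions$fold == f])
    tr_pids <- names(plan$outer)[plan$outer != f]
    expect_length(intersect(te_pids, tr_pids), 0)
  }
})

test_that("constant targets are fit trivially and NaN features abort", {
  co <- small_cohort(12, seed = 63)
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 16, seed = 5)
  x <- build_modality_matrix(co, pr, mt$diary_id)
  plan <- build_fold_plan(unique(mt$participant_id), seed = 6)
  y <- rep(10, nrow(mt))
  res <- fit_eval_single(x, y, mt$participant_id, plan,
                         search_space(budget = 0), "const")
  expect_lt(res$mae_mean, 0.6) # epsilon-insensitive tube allows ~epsilon
  xb <- x; xb[3, 2] <- NaN
  expect_error(fit_eval_single(xb, mt$bdi_sum, mt$participant_id, plan,
                               search_space(budget = 0), "m"),
               "feature columns")
})

test_that("dummy regressor predicts the training mean with R2 <= 0", {
  withr::with_seed(3, {
    y <- rnorm(100, 20, 5)
    pid <- sprintf("P%02d", rep(1:20, each = 5))
    plan <- build_fold_plan(unique(pid), seed = 1)
    res <- dummy_regressor(y, pid, plan)
    # MAE close to the mean absolute deviation from the mean
    expect_equal(res$mae_mean, mean(abs(y - mean(y))), tolerance = 0.15)
    expect_lt(res$r2_mean, 0.05)
    f1 <- res$predictions$fold == 1
    expect_equal(unique(res$predictions$y_pred[f1]),
                 mean(y[res$predictions$fold != 1]))
  })
})

test_that("rank AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    for (i in 1:5) {
      truth <- factor(sample(c("MDD", "HC"), 60, replace = TRUE))
      score <- rnorm(60) + (truth == "MDD")
      ref <- as.numeric(suppressMessages(
        pROC::auc(pROC::roc(truth, score, levels = c("HC", "MDD"),
                            direction = "<"))))
      expect_equal(voicebdi:::auroc(truth, score, "MDD"), ref,
                   tolerance = 1e-12)
    }
  })
})

test_that("stratified dummy classifier sits at chance balanced accuracy", {
  withr::with_seed(5, {
    pid <- sprintf("P%02d", 1:40)
    labels <- rep(c("MDD", "HC"), 20)
    plan <- build_fold_plan(pid, seed = 2)
    baccs <- vapply(1:50, function(i) {
      dummy_classifier(labels, pid, plan, seed = i)$bacc_mean
    }, numeric(1))
    expect_lt(abs(mean(baccs) - 0.5), 0.05)
  })
})

test_that("fusing a modality with itself matches the single modality", {
  co <- small_cohort(25, seed = 67)
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 32, seed = 5, target_r2 = 0.4)
  x <- build_modality_matrix(co, pr, mt$diary_id)
  plan <- build_fold_plan(unique(mt$participant_id), seed = 6)
  sp <- search_space(budget = 3)
  single <- fit_eval_single(x, mt$bdi_sum, mt$participant_id, plan, sp, "s")
  fused <- stacked_fusion(list(a = x, b = x), mt$bdi_sum, mt$participant_id,
                          plan, sp, "f")
  expect_lt(abs(fused$mae_mean - single$mae_mean),
            2.5 * max(single$mae_sd, 0.5))
  expect_error(stacked_fusion(list(a = x), mt$bdi_sum, mt$participant_id,
                              plan, sp), "length")
  expect_error(stacked_fusion(list(a = x, b = x[-1, ]), mt$bdi_sum,
                              mt$participant_id, plan, sp),
               "row mismatch")
})

test_that("fusing signal with pure noise does not destroy the signal", {
  co <- generate_cohort(cohort_config(n_participants = 40, seed = 69,
                                      adherence_log_mean = log(3),
                                      adherence_log_sd = 0.5))
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 32, seed = 5, target_r2 = 0.5)
  x <- build_modality_matrix(co, pr, mt$diary_id)
  noise <- withr::with_seed(7, {
    matrix(rnorm(nrow(mt) * 16), nrow(mt), 16,
           dimnames = list(mt$diary_id, NULL))
  })
  plan <- build_fold_plan(unique(mt$participant_id), seed = 6)
  sp <- search_space(budget = 3)
  single <- fit_eval_single(x, mt$bdi_sum, mt$participant_id, plan, sp, "s")
  fused <- stacked_fusion(list(sig = x, noise = noise), mt$bdi_sum,
                          mt$participant_id, plan, sp, "f")
  expect_gt(fused$r2_mean, single$r2_mean - 0.1)
})

test_that("classification separates groups and rejects single-class folds", {
  co <- generate_cohort(cohort_config(n_participants = 40, seed = 71,
                                      adherence_log_mean = log(3),
                                      adherence_log_sd = 0.4,
                                      severity_mean_mdd = 25,
                                      severity_mean_hc = 2,
                                      severity_sd = c(2, 2)))
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 32, seed = 5, beta = 2, noise_sd = 0.3)
  x <- build_modality_matrix(co, pr, mt$diary_id)
  pid_group <- co$participants$group[match(unique(mt$participant_id),
                                           co$participants$participant_id)]
  plan <- build_fold_plan(unique(mt$participant_id), seed = 6,
                          strata = pid_group)
  res <- classify_mdd_hc(x, mt$group, mt$participant_id, plan,
                         search_space(budget = 3))
  expect_gt(res$bacc_mean, 0.9) # well-separated construction
  expect_gt(res$auroc_mean, 0.95)
  # label-shuffled labels sit near chance
  y_shuf <- withr::with_seed(9, {
    pid <- unique(mt$participant_id)
    g <- sample(pid_group)
    factor(g[match(mt$participant_id, pid)])
  })
  res0 <- classify_mdd_hc(x, y_shuf, mt$participant_id, plan,
                          search_space(budget = 2))
  expect_lt(abs(res0$bacc_mean - 0.5), 0.15)
})

test_that("subgroup rerun rebuilds the plan and behaves as control", {
  co <- generate_cohort(cohort_config(n_participants = 50, seed = 73,
                                      adherence_log_mean = log(3),
                                      adherence_log_sd = 0.5))
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 32, seed = 5, target_r2 = 0.4)
  x <- build_modality_matrix(co, pr, mt$diary_id)
  full_plan <- build_fold_plan(unique(mt$participant_id), seed = 6)
  mdd <- subgroup_rerun(co, x, "MDD", search_space(budget = 2), seed = 6)
  expect_false(identical(mdd$plan_hash, full_plan$plan_hash))
  expect_equal(sort(mdd$predictions$diary_id),
               sort(mt$diary_id[mt$group == "MDD"]))
  hc <- subgroup_rerun(co, x, "HC", search_space(budget = 2), seed = 6)
  # negative control: low-variance HC scores leave little to predict
  expect_lt(hc$r2_mean, 0.35)
})

test_that("idiographic tracking finds planted within-person signal", {
  co <- generate_cohort(cohort_config(n_participants = 12, seed = 77,
                                      adherence_log_mean = log(50),
                                      adherence_log_sd = 0,
                                      ar_coefficient = 0.3,
                                      theme_severity_slopes = rep(0, 6)))
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 32, seed = 5, beta = 2, noise_sd = 0.5)
  x <- build_modality_matrix(co, pr, mt$diary_id)
  res <- idiographic_delta(co, x, min_entries = 10)
  expect_gt(nrow(res$per_subject), 8)
  # majority of subjects track change positively
  expect_gt(mean(res$per_subject$cor_model > 0, na.rm = TRUE), 0.5)
  # model beats the no-change baseline on average
  expect_lt(mean(res$per_subject$mae_model),
            mean(res$per_subject$mae_nochange))
  expect_true(all(c(3, 5, 7) %in% res$detection$threshold))
})

test_that("constant series leave the no-change baseline unbeatable", {
  co <- generate_cohort(cohort_config(n_participants = 6, seed = 79,
                                      adherence_log_mean = log(15),
                                      adherence_log_sd = 0,
                                      severity_mean_mdd = 12.2,
                                      severity_mean_hc = 3.2,
                                      severity_sd = c(0.01, 0.01),
                                      bdi_noise_sd = 0))
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 16, seed = 5, beta = 0, noise_sd = 1)
  x <- build_modality_matrix(co, pr, mt$diary_id)
  res <- idiographic_delta(co, x, min_entries = 10)
  expect_true(all(res$per_subject$mae_nochange < 1e-9))
  expect_true(all(res$per_subject$mae_model >=
                    res$per_subject$mae_nochange - 1e-9))
})

test_that("a single +8 jump is exactly one deterioration event at 7", {
  dy <- c(0, 1, -1, 8, 0, -2)
  expect_equal(sum(dy >= 7), 1)
  expect_equal(sum(dy >= 5), 1)
  expect_equal(sum(dy >= 3), 1)
})
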