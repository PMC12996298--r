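#' @name benchmark
#' @title Participant-grouped nested CV, PCA/SVR pipeline, fusion, subgroup
#'   and idiographic analyses
#'
#' @description
#' The modelling engine: a shared participant-grouped fold plan (5 outer /
#' 3 inner), a z-score -> PCA -> SVR pipeline tuned by randomized search
#' with a fixed budget per outer fold, dummy baselines, stacked late fusion
#' with a ridge meta-learner on inner out-of-fold predictions, a diagnostic
#' classifier, subgroup reruns, and per-person change tracking.
NULL

#' Paired modelling table for a cohort
#'
#' Diaries with a BDI self-report within the pairing window, joined with the
#' diagnostic group, ordered by diary id.
#'
#' @param cohort a `voicebdi_cohort`.
#' @param window_days pairing window.
#' @return data.frame with diary_id, participant_id, group, bdi_sum,
#'   timestamp.
#' @export
modeling_table <- function(cohort, window_days = 7) {
  paired <- pair_bdi(cohort$diaries, cohort$bdi, window_days)
  paired <- merge(paired,
                  cohort$participants[, c("participant_id", "group")],
                  by = "participant_id")
  out <- paired[paired$paired,
                c("diary_id", "participant_id", "group", "bdi_sum",
                  "timestamp")]
  out[order(out$diary_id), ]
}

# Deal units round-robin into k balanced groups after a seeded shuffle,
# optionally within strata so every fold sees every stratum.
deal_groups <- function(units, k, seed, strata = NULL) {
  assign <- integer(length(units))
  names(assign) <- units
  with_seed(seed, {
    if (is.null(strata)) strata <- rep(1L, length(units))
    offset <- 0L
    for (s in unique(strata)) {
      u <- units[strata == s]
      u <- u[sample(length(u))]
      assign[u] <- ((seq_along(u) - 1L + offset) %% k) + 1L
      offset <- offset + length(u)
    }
  })
  assign
}

#' Build a participant-grouped nested fold plan
#'
#' Participants are assigned to `n_outer` disjoint outer folds balanced by
#' participant count (diary counts may differ); for each outer fold, the
#' remaining participants are split into `n_inner` inner folds. The same
#' plan is reused identically across all models; `plan_hash` fingerprints it
#' so downstream paired comparisons can enforce identity.
#'
#' @param participants character vector of participant ids.
#' @param n_outer,n_inner outer and inner fold counts.
#' @param seed integer seed; deterministic plans.
#' @param strata optional per-participant stratum labels (e.g. diagnostic
#'   group) so that every fold contains every stratum — required for the
#'   classification analysis.
#' @return a `voicebdi_fold_plan`.
#' @export
build_fold_plan <- function(participants, n_outer = 5, n_inner = 3,
                            seed = 1L, strata = NULL) {
  participants <- as.character(participants)
  if (length(participants) < n_outer) {
    stop("fewer participants than outer folds", call. = FALSE)
  }
  if (!is.null(strata)) {
    stopifnot(length(strata) == length(participants))
    tab <- table(strata)
    if (any(tab < n_outer)) {
      stop("a stratum has fewer participants than outer folds",
           call. = FALSE)
    }
  }
  outer <- deal_groups(participants, n_outer,
                       substream_seed(seed, "outer"), strata)
  inner <- lapply(seq_len(n_outer), function(f) {
    tr <- participants[outer != f]
    st <- if (is.null(strata)) NULL else strata[outer != f]
    deal_groups(tr, n_inner, substream_seed(seed, paste0("inner/", f)), st)
  })
  plan <- list(outer = outer, inner = inner, n_outer = n_outer,
               n_inner = n_inner, seed = as.integer(seed),
               grouped = TRUE)
  plan$plan_hash <- object_hash(plan[c("outer", "inner")])
  class(plan) <- "voicebdi_fold_plan"
  plan
}

#' Deliberately ungrouped fold plan (diagnostic only)
#'
#' Assigns folds at the diary level, ignoring participant identity. This
#' leaks speaker identity across train/test and exists solely to demonstrate
#' the inflation that participant grouping prevents. Never use for reported
#' results.
#'
#' @param diary_ids diary identifiers.
#' @param n_outer,n_inner fold counts.
#' @param seed integer seed.
#' @return a `voicebdi_fold_plan` with `grouped = FALSE`.
#' @export
build_ungrouped_fold_plan <- function(diary_ids, n_outer = 5, n_inner = 3,
                                      seed = 1L) {
  plan <- build_fold_plan(as.character(diary_ids), n_outer, n_inner, seed)
  plan$grouped <- FALSE
  plan$plan_hash <- object_hash(plan[c("outer", "inner", "grouped")])
  plan
}

# Fold key per diary: participant id under a grouped plan, diary id under
# the diagnostic ungrouped plan.
fold_keys <- function(plan, participant_ids, diary_ids) {
  if (isTRUE(plan$grouped)) participant_ids else diary_ids
}

#' Randomized-search space for the PCA/SVR pipeline
#'
#' @param budget candidate draws per outer fold (0 = fixed default
#'   configuration, no inner search — used by permutation reruns).
#' @param kernels SVR kernels to sample from.
#' @param c_range,epsilon_range log-uniform sampling ranges for C and the
#'   epsilon-insensitive width.
#' @param pca_grid candidate PCA dimensionalities (filtered per fold to at
#'   most min(n_features, n_train) - 1).
#' @return a `voicebdi_search_space`.
#' @export
search_space <- function(budget = 30,
                         kernels = c("radial", "linear"),
                         c_range = c(1e-2, 1e3),
                         epsilon_range = c(1e-3, 10),
                         pca_grid = c(2, 5, 10, 20, 30, 50)) {
  structure(list(budget = budget, kernels = kernels, c_range = c_range,
                 epsilon_range = epsilon_range, pca_grid = pca_grid),
            class = "voicebdi_search_space")
}

draw_candidates <- function(space, n_features, n_train, seed) {
  kmax <- min(n_features, n_train) - 1L
  grid <- space$pca_grid[space$pca_grid <= kmax]
  if (length(grid) == 0) grid <- max(1L, kmax)
  if (space$budget == 0) {
    return(list(list(kernel = "radial", cost = 10, epsilon = 0.5,
                     ncomp = min(10, max(grid)))))
  }
  with_seed(seed, {
    lapply(seq_len(space$budget), function(i) {
      kernel <- sample(space$kernels, 1L)
      cmax <- space$c_range[2]
      # libsvm's linear solver converges poorly when weak regularisation
      # meets collinear features; keep the linear arm in its useful regime
      if (kernel == "linear") cmax <- min(cmax, 32)
      list(kernel = kernel,
           cost = exp(stats::runif(1, log(space$c_range[1]), log(cmax))),
           epsilon = exp(stats::runif(1, log(space$epsilon_range[1]),
                                      log(space$epsilon_range[2]))),
           ncomp = sample(grid, 1L))
    })
  })
}

# z-score + PCA fit on the training rows only.
fit_preproc <- function(x_train, ncomp) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  xs <- sweep(sweep(x_train, 2, mu), 2, sd, `/`)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE, rank. = ncomp)
  list(mu = mu, sd = sd, rotation = pc$rotation,
       transform = function(x) {
     sweep(sweep(x, 2, mu), 2, sd, `/`) %*% pc$rotation
   })
}

fit_predict_svr <- function(x_train, y_train, x_test, params) {
  pp <- fit_preproc(x_train, params$ncomp)
  zt <- pp$transform(x_train)
  fit <- tryCatch(
    e1071::svm(zt, y_train, type = "eps-regression",
               kernel = params$kernel, cost = params$cost,
               epsilon = params$epsilon, scale = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$tot.nSV == 0) {
    # every target inside the epsilon tube: the fit is the constant mean
    return(rep(mean(y_train), nrow(x_test)))
  }
  as.numeric(stats::predict(fit, pp$transform(x_test)))
}

fit_predict_svc <- function(x_train, y_train, x_test, params) {
  pp <- fit_preproc(x_train, params$ncomp)
  zt <- pp$transform(x_train)
  fit <- e1071::svm(zt, y_train, type = "C-classification",
                    kernel = params$kernel, cost = params$cost,
                    scale = FALSE)
  pr <- stats::predict(fit, pp$transform(x_test), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pos <- levels(y_train)[1]
  score <- if (startsWith(colnames(dv)[1], paste0(pos, "/"))) {
    dv[, 1]
  } else {
    -dv[, 1]
  }
  list(class = pr, score = as.numeric(score), positive = pos)
}

# Feature access: x is either a matrix aligned to ids, or a builder
# function(train_ids, test_ids) -> list(train =, test =) for modalities that
# must be refit on training partitions (TF-IDF).
get_xy <- function(x, ids, train_idx, test_idx) {
  if (is.function(x)) {
    x(ids[train_idx], ids[test_idx])
  } else {
    list(train = x[train_idx, , drop = FALSE],
         test = x[test_idx, , drop = FALSE])
  }
}

check_features <- function(x) {
  if (is.function(x)) return(invisible(TRUE))
  bad <- which(!stats::complete.cases(t(x)))
  if (length(bad)) {
    stop("non-finite values in feature columns: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Inner-loop randomized search on one outer-training split. All arguments
# are already restricted to the outer-training rows: x is the training
# feature matrix (or a builder plus the training diary ids), y the training
# targets, keys the training fold keys. Returns the winning candidate (by
# inner-CV MAE) and optionally the inner out-of-fold predictions under it.
inner_search <- function(x, ids, y, keys, inner_assign, space, seed,
                         want_oof = FALSE) {
  cands <- draw_candidates(space,
                           n_features = if (is.function(x)) Inf else ncol(x),
                           n_train = length(ids), seed = seed)
  inner_f <- inner_assign[keys]
  folds <- sort(unique(inner_f))
  # features are independent of the candidate: build once per inner fold
  splits <- lapply(folds, function(j) {
    tr <- which(inner_f != j)
    va <- which(inner_f == j)
    list(tr = tr, va = va, xy = get_xy(x, ids, tr, va))
  })
  if (length(cands) == 1L) {
    best <- cands[[1]]
  } else {
    scores <- vapply(cands, function(p) {
      errs <- vapply(splits, function(s) {
        p2 <- p
        p2$ncomp <- min(p$ncomp, ncol(s$xy$train), length(s$tr) - 1L)
        yh <- fit_predict_svr(s$xy$train, y[s$tr], s$xy$test, p2)
        mae(y[s$va], yh)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    best <- cands[[which.min(scores)]]
  }
  oof <- NULL
  if (want_oof) {
    oof <- rep(NA_real_, length(ids))
    for (s in splits) {
      p2 <- best
      p2$ncomp <- min(best$ncomp, ncol(s$xy$train), length(s$tr) - 1L)
      oof[s$va] <- fit_predict_svr(s$xy$train, y[s$tr], s$xy$test, p2)
    }
  }
  list(best = best, oof = oof)
}

new_benchmark_result <- function(model_name, fold_ids, fold_mae, fold_r2,
                                 predictions, plan, extras = list()) {
  res <- c(list(model = model_name,
                fold_mae = fold_mae, fold_r2 = fold_r2,
                mae_mean = mean(fold_mae), mae_sd = stats::sd(fold_mae),
                r2_mean = mean(fold_r2), r2_sd = stats::sd(fold_r2),
                predictions = predictions,
                plan_hash = plan$plan_hash),
           extras)
  class(res) <- "voicebdi_benchmark_result"
  res
}

#' @export
print.voicebdi_benchmark_result <- function(x, ...) {
  cat(sprintf("%s: MAE = %.2f (%.2f), R2 = %.2f (%.2f) over %d folds\n",
              x$model, x$mae_mean, x$mae_sd, x$r2_mean, x$r2_sd,
              length(x$fold_mae)))
  invisible(x)
}

#' Fit and evaluate a single-modality model under nested grouped CV
#'
#' Per outer fold: a randomized search over the PCA/SVR space scored by
#' inner-CV MAE, the winner refit on the full outer-training split and
#' evaluated once on the outer-test split. Scaler and PCA are learned on
#' training partitions only.
#'
#' @param x modality matrix (rows aligned to `targets`) or a builder
#'   function(train_ids, test_ids) for train-partition-refit features.
#' @param targets numeric BDI sums, one per diary.
#' @param participant_ids grouping variable, one per diary.
#' @param plan a fold plan from [build_fold_plan()].
#' @param space a [search_space()].
#' @param model_name label for reports.
#' @param diary_ids diary identifiers (default from rownames).
#' @param seed seed for the candidate draws (defaults to the plan seed).
#' @return a `voicebdi_benchmark_result` with per-fold MAE/R2 (mean and SD
#'   over folds) and the concatenated out-of-fold `predictions`.
#' @export
fit_eval_single <- function(x, targets, participant_ids, plan,
                            space = search_space(), model_name = "model",
                            diary_ids = NULL, seed = plan$seed) {
  check_features(x)
  if (is.null(diary_ids)) {
    diary_ids <- if (!is.function(x) && !is.null(rownames(x))) {
      rownames(x)
    } else {
      as.character(seq_along(targets))
    }
  }
  keys <- fold_keys(plan, as.character(participant_ids), diary_ids)
  outer_f <- plan$outer[keys]
  if (anyNA(outer_f)) stop("fold plan does not cover all rows", call. = FALSE)
  folds <- seq_len(plan$n_outer)
  preds <- data.frame(diary_id = diary_ids, y_true = targets,
                      y_pred = NA_real_, fold = outer_f,
                      stringsAsFactors = FALSE)
  fold_mae <- fold_r2 <- numeric(plan$n_outer)
  best_params <- vector("list", plan$n_outer)
  for (f in folds) {
    tr <- which(outer_f != f)
    te <- which(outer_f == f)
    x_tr <- if (is.function(x)) x else x[tr, , drop = FALSE]
    sr <- inner_search(x_tr, diary_ids[tr], targets[tr], keys[tr],
                       plan$inner[[f]], space,
                       seed = substream_seed(seed, paste0("cand/", f)))
    xy <- get_xy(x, diary_ids, tr, te)
    p2 <- sr$best
    p2$ncomp <- min(p2$ncomp, ncol(xy$train), length(tr) - 1L)
    yh <- fit_predict_svr(xy$train, targets[tr], xy$test, p2)
    preds$y_pred[te] <- yh
    fold_mae[f] <- mae(targets[te], yh)
    fold_r2[f] <- rsq(targets[te], yh)
    best_params[[f]] <- sr$best
  }
  new_benchmark_result(model_name, folds, fold_mae, fold_r2, preds, plan,
                       list(best_params = best_params))
}

#' Mean-prediction dummy regressor
#'
#' Predicts the outer-training mean for every outer-test diary.
#'
#' @inheritParams fit_eval_single
#' @return a `voicebdi_benchmark_result`.
#' @export
dummy_regressor <- function(targets, participant_ids, plan,
                            diary_ids = as.character(seq_along(targets))) {
  keys <- fold_keys(plan, as.character(participant_ids), diary_ids)
  outer_f <- plan$outer[keys]
  preds <- data.frame(diary_id = diary_ids, y_true = targets,
                      y_pred = NA_real_, fold = outer_f,
                      stringsAsFactors = FALSE)
  fold_mae <- fold_r2 <- numeric(plan$n_outer)
  for (f in seq_len(plan$n_outer)) {
    te <- which(outer_f == f)
    m <- mean(targets[outer_f != f])
    preds$y_pred[te] <- m
    fold_mae[f] <- mae(targets[te], m + numeric(length(te)))
    fold_r2[f] <- rsq(targets[te], rep(m, length(te)))
  }
  new_benchmark_result("dummy_mean", seq_len(plan$n_outer), fold_mae,
                       fold_r2, preds, plan)
}

#' Stratified dummy classifier
#'
#' Samples labels at the outer-training prevalence.
#'
#' @param labels factor of class labels per diary.
#' @inheritParams fit_eval_single
#' @return list with per-fold balanced accuracy and its mean/SD.
#' @export
dummy_classifier <- function(labels, participant_ids, plan, seed = 1L,
                             diary_ids = as.character(seq_along(labels))) {
  labels <- factor(labels)
  keys <- fold_keys(plan, as.character(participant_ids), diary_ids)
  outer_f <- plan$outer[keys]
  bacc <- with_seed(substream_seed(seed, "dummy_clf"), {
    vapply(seq_len(plan$n_outer), function(f) {
      tr <- labels[outer_f != f]
      te <- labels[outer_f == f]
      prev <- table(tr) / length(tr)
      yh <- factor(sample(names(prev), length(te), replace = TRUE,
                          prob = as.numeric(prev)), levels = levels(labels))
      balanced_accuracy(te, yh)
    }, numeric(1))
  })
  list(model = "dummy_stratified", fold_bacc = bacc,
       bacc_mean = mean(bacc), bacc_sd = stats::sd(bacc))
}

balanced_accuracy <- function(truth, pred) {
  lv <- levels(factor(truth))
  mean(vapply(lv, function(l) {
    idx <- truth == l
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == l)
  }, numeric(1)), na.rm = TRUE)
}

# Rank-based AUROC of score for the positive class.
auroc <- function(truth, score, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stacked late fusion of several modalities
#'
#' Within each outer-training split, modality-specific base models (each
#' tuned by its own randomized search) produce inner out-of-fold predictions
#' that form the meta-feature table for a ridge meta-learner (unpenalised
#' intercept; penalty chosen on the meta-features by inner-fold CV). Base
#' models are then refit on the full outer-training split; outer-test
#' meta-features are the refit base predictions, and reported metrics come
#' from the meta-learner's outer-fold predictions.
#'
#' @param xs named list of modality matrices (or builder functions), rows
#'   aligned to `targets`.
#' @inheritParams fit_eval_single
#' @param lambda_grid ridge penalty grid for the meta-learner.
#' @return a `voicebdi_benchmark_result`.
#' @export
stacked_fusion <- function(xs, targets, participant_ids, plan,
                           space = search_space(), model_name = "fusion",
                           diary_ids = NULL, seed = plan$seed,
                           lambda_grid = 10^seq(-3, 2)) {
  stopifnot(length(xs) >= 2)
  for (x in xs) check_features(x)
  dims <- vapply(xs, function(x) if (is.function(x)) -1L else nrow(x),
                 integer(1))
  if (any(dims[dims > 0] != length(targets))) {
    stop("modality row mismatch", call. = FALSE)
  }
  if (is.null(diary_ids)) {
    rn <- Filter(Negate(is.null),
                 lapply(xs, function(x) if (!is.function(x)) rownames(x)))
    diary_ids <- if (length(rn)) rn[[1]] else
      as.character(seq_along(targets))
  }
  keys <- fold_keys(plan, as.character(participant_ids), diary_ids)
  outer_f <- plan$outer[keys]
  preds <- data.frame(diary_id = diary_ids, y_true = targets,
                      y_pred = NA_real_, fold = outer_f,
                      stringsAsFactors = FALSE)
  fold_mae <- fold_r2 <- numeric(plan$n_outer)
  for (f in seq_len(plan$n_outer)) {
    tr <- which(outer_f != f)
    te <- which(outer_f == f)
    z_tr <- matrix(NA_real_, length(tr), length(xs))
    z_te <- matrix(NA_real_, length(te), length(xs))
    for (m in seq_along(xs)) {
      x_tr <- if (is.function(xs[[m]])) xs[[m]] else
        xs[[m]][tr, , drop = FALSE]
      sr <- inner_search(x_tr, diary_ids[tr], targets[tr], keys[tr],
                         plan$inner[[f]], space,
                         seed = substream_seed(seed,
                                               paste0("cand/", f, "/", m)),
                         want_oof = TRUE)
      z_tr[, m] <- sr$oof
      xy <- get_xy(xs[[m]], diary_ids, tr, te)
      p2 <- sr$best
      p2$ncomp <- min(p2$ncomp, ncol(xy$train), length(tr) - 1L)
      z_te[, m] <- fit_predict_svr(xy$train, targets[tr], xy$test, p2)
    }
    lam <- choose_ridge_lambda(z_tr, targets[tr],
                               plan$inner[[f]][keys[tr]], lambda_grid)
    rb <- ridge_fit(z_tr, targets[tr], lam)
    yh <- ridge_predict(rb, z_te)
    preds$y_pred[te] <- yh
    fold_mae[f] <- mae(targets[te], yh)
    fold_r2[f] <- rsq(targets[te], yh)
  }
  new_benchmark_result(model_name, seq_len(plan$n_outer), fold_mae, fold_r2,
                       preds, plan)
}

# Ridge with unpenalised intercept via centring.
ridge_fit <- function(x, y, lambda) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  my <- mean(y)
  beta <- solve(crossprod(xc) + diag(lambda, ncol(x)),
                crossprod(xc, y - my))
  list(beta = beta, intercept = my - as.numeric(mu %*% beta), lambda = lambda)
}

ridge_predict <- function(fit, x) {
  as.numeric(as.matrix(x) %*% fit$beta) + fit$intercept
}

choose_ridge_lambda <- function(x, y, fold_of_row, lambda_grid) {
  folds <- sort(unique(fold_of_row))
  if (length(folds) < 2) return(lambda_grid[1])
  errs <- vapply(lambda_grid, function(l) {
    mean(vapply(folds, function(j) {
      tr <- fold_of_row != j
      fit <- ridge_fit(x[tr, , drop = FALSE], y[tr], l)
      mae(y[!tr], ridge_predict(fit, x[!tr, , drop = FALSE]))
    }, numeric(1)))
  }, numeric(1))
  lambda_grid[which.min(errs)]
}

#' MDD vs HC classification under the same nested protocol
#'
#' A margin classifier (SVC) on the PCA-reduced standardized features, tuned
#' by inner-CV balanced accuracy; AUROC comes from decision scores.
#'
#' @param x modality matrix.
#' @param labels factor per diary ("MDD"/"HC"); the first level of
#'   `positive` is scored.
#' @inheritParams fit_eval_single
#' @param positive positive class for AUROC.
#' @return list with per-fold balanced accuracy and AUROC, means and SDs.
#' @export
classify_mdd_hc <- function(x, labels, participant_ids, plan,
                            space = search_space(), positive = "MDD",
                            diary_ids = NULL, seed = plan$seed) {
  check_features(x)
  labels <- stats::relevel(factor(labels), ref = positive)
  if (is.null(diary_ids)) {
    diary_ids <- if (!is.null(rownames(x))) rownames(x) else
      as.character(seq_along(labels))
  }
  keys <- fold_keys(plan, as.character(participant_ids), diary_ids)
  outer_f <- plan$outer[keys]
  for (f in seq_len(plan$n_outer)) {
    if (length(unique(labels[outer_f != f])) < 2) {
      stop("single-class outer-training split; rebuild the plan with strata",
           call. = FALSE)
    }
  }
  bacc <- auc <- numeric(plan$n_outer)
  for (f in seq_len(plan$n_outer)) {
    tr <- which(outer_f != f)
    te <- which(outer_f == f)
    cands <- draw_candidates(space, ncol(x), length(tr),
                             substream_seed(seed, paste0("cand/", f)))
    inner_f <- plan$inner[[f]][keys[tr]]
    folds <- sort(unique(inner_f))
    if (length(cands) > 1L) {
      scores <- vapply(cands, function(p) {
        mean(vapply(folds, function(j) {
          itr <- tr[inner_f != j]
          iva <- tr[inner_f == j]
          if (length(unique(labels[itr])) < 2) return(NA_real_)
          p2 <- p
          p2$ncomp <- min(p$ncomp, ncol(x), length(itr) - 1L)
          cl <- fit_predict_svc(x[itr, , drop = FALSE], labels[itr],
                                x[iva, , drop = FALSE], p2)
          balanced_accuracy(labels[iva], cl$class)
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      best <- cands[[which.max(scores)]]
    } else {
      best <- cands[[1]]
    }
    best$ncomp <- min(best$ncomp, ncol(x), length(tr) - 1L)
    cl <- fit_predict_svc(x[tr, , drop = FALSE], labels[tr],
                          x[te, , drop = FALSE], best)
    bacc[f] <- balanced_accuracy(labels[te], cl$class)
    auc[f] <- auroc(labels[te], cl$score, positive)
  }
  list(model = "svc", fold_bacc = bacc, fold_auroc = auc,
       bacc_mean = mean(bacc), bacc_sd = stats::sd(bacc),
       auroc_mean = mean(auc, na.rm = TRUE),
       auroc_sd = stats::sd(auc, na.rm = TRUE), plan_hash = plan$plan_hash)
}

#' Re-run the regression pipeline within one diagnostic subgroup
#'
#' The fold plan is rebuilt within the subgroup; everything else is
#' identical. The HC-only rerun serves as a negative control (little true
#' variance to predict); the MDD-only rerun probes within-clinical-cohort
#' signal.
#'
#' @param cohort a `voicebdi_cohort`.
#' @param x modality matrix over the full cohort's paired diaries.
#' @param subgroup "MDD" or "HC".
#' @inheritParams fit_eval_single
#' @return a `voicebdi_benchmark_result` (plus the subgroup plan).
#' @export
subgroup_rerun <- function(cohort, x, subgroup = c("MDD", "HC"),
                           space = search_space(), n_outer = 5, n_inner = 3,
                           seed = 1L, model_name = NULL) {
  subgroup <- match.arg(subgroup)
  mt <- modeling_table(cohort)
  mt <- mt[mt$group == subgroup, ]
  if (nrow(mt) == 0) stop("empty subgroup", call. = FALSE)
  plan <- build_fold_plan(unique(mt$participant_id), n_outer, n_inner, seed)
  xs <- x[mt$diary_id, , drop = FALSE]
  fit_eval_single(xs, mt$bdi_sum, mt$participant_id, plan, space,
                  model_name = model_name %||%
                    paste0(subgroup, "_only"),
                  diary_ids = mt$diary_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Idiographic change tracking for frequent diarists
#'
#' For each participant with at least `min_entries` paired diaries: a
#' chronological train/test split, a ridge model on embedding principal
#' components predicting the week-to-week BDI change (delta), per-subject
#' correlation and MAE against a no-change baseline (delta = 0) and a
#' calibrated global model (global ridge fit on non-frequent participants,
#' per-subject offset calibrated on the training segment), and deterioration
#' detection sensitivity/specificity at each threshold.
#'
#' @param cohort a `voicebdi_cohort`.
#' @param x modality matrix over paired diaries.
#' @param min_entries minimum paired diaries per idiographic subject.
#' @param thresholds deterioration thresholds on delta-BDI.
#' @param train_frac chronological training fraction.
#' @param n_pcs principal components for the person-level model.
#' @param lambda ridge penalty.
#' @return list with `per_subject`, `detection`, and `skipped`.
#' @export
idiographic_delta <- function(cohort, x, min_entries = 10,
                              thresholds = c(3, 5, 7), train_frac = 0.7,
                              n_pcs = 5, lambda = 1) {
  mt <- modeling_table(cohort)
  mt <- mt[order(mt$participant_id, mt$timestamp), ]
  counts <- table(mt$participant_id)
  frequent <- names(counts)[counts >= min_entries]
  skipped <- names(counts)[counts < min_entries]
  if (length(frequent) == 0) {
    return(list(per_subject = NULL, detection = NULL, skipped = skipped))
  }
  # global model on non-frequent participants, for the calibrated baseline
  glob_mt <- mt[!(mt$participant_id %in% frequent), ]
  glob <- NULL
  if (nrow(glob_mt) >= 20) {
    gx <- x[glob_mt$diary_id, , drop = FALSE]
    pp <- fit_preproc(gx, min(n_pcs, ncol(gx), nrow(gx) - 1L))
    gz <- pp$transform(gx)
    gfit <- ridge_fit(gz, glob_mt$bdi_sum, lambda)
    glob <- list(pp = pp, fit = gfit)
  }
  per_subject <- list()
  det <- list()
  for (p in frequent) {
    sm <- mt[mt$participant_id == p, ]
    y <- sm$bdi_sum
    dy <- diff(y)
    n_d <- length(dy)
    n_tr <- max(2L, ceiling(train_frac * n_d))
    if (n_d - n_tr < 1) n_tr <- n_d - 1L
    emb <- x[sm$diary_id, , drop = FALSE]
    dx <- emb[-1, , drop = FALSE] - emb[-nrow(emb), , drop = FALSE]
    k <- min(n_pcs, ncol(dx), n_tr - 1L)
    pred <- rep(0, n_d - n_tr)
    if (k >= 1) {
      pp <- fit_preproc(dx[seq_len(n_tr), , drop = FALSE], k)
      fit <- ridge_fit(pp$transform(dx[seq_len(n_tr), , drop = FALSE]),
                       dy[seq_len(n_tr)], lambda)
      pred <- ridge_predict(fit,
                            pp$transform(dx[-seq_len(n_tr), , drop = FALSE]))
    }
    dy_te <- dy[-seq_len(n_tr)]
    glob_pred <- rep(NA_real_, length(dy_te))
    if (!is.null(glob)) {
      gz <- glob$pp$transform(emb)
      yh <- ridge_predict(glob$fit, gz)
      offset <- mean(y[seq_len(n_tr + 1L)] - yh[seq_len(n_tr + 1L)])
      yh <- yh + offset
      glob_pred <- diff(yh)[-seq_len(n_tr)]
    }
    cor_model <- if (stats::sd(dy_te) > 0 && stats::sd(pred) > 0) {
      stats::cor(dy_te, pred)
    } else {
      NA_real_
    }
    per_subject[[p]] <- data.frame(
      participant_id = p, n_entries = nrow(sm), n_test = length(dy_te),
      cor_model = cor_model,
      mae_model = mae(dy_te, pred),
      mae_nochange = mae(dy_te, 0 * dy_te),
      mae_global = if (all(is.na(glob_pred))) NA_real_ else
        mae(dy_te, glob_pred),
      stringsAsFactors = FALSE)
    for (th in thresholds) {
      det[[paste(p, th)]] <- data.frame(
        threshold = th,
        true_events = sum(dy_te >= th),
        pred_events = sum(pred >= th),
        hits = sum(dy_te >= th & pred >= th),
        correct_rejections = sum(dy_te < th & pred < th),
        n = length(dy_te))
    }
  }
  per_subject <- do.call(rbind, per_subject)
  rownames(per_subject) <- NULL
  det <- do.call(rbind, det)
  detection <- do.call(rbind, lapply(split(det, det$threshold), function(d) {
    pos <- sum(d$true_events)
    neg <- sum(d$n) - pos
    data.frame(threshold = d$threshold[1],
               sensitivity = if (pos > 0) sum(d$hits) / pos else NA_real_,
               specificity = if (neg > 0) {
                 sum(d$correct_rejections) / neg
               } else {
                 NA_real_
               },
               n_events = pos)
  }))
  rownames(detection) <- NULL
  list(per_subject = per_subject, detection = detection, skipped = skipped)
}
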