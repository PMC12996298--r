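#' @name stats_module
#' @title Permutation nulls, effect sizes, bootstrap CIs, multiplicity
NULL

#' Per-fold paired differences between two models
#'
#' Enforces that both models were evaluated on the identical fold plan.
#'
#' @param model_a,model_b model names.
#' @param metric metric name.
#' @param d numeric vector of per-outer-fold differences (a minus b).
#' @param hash_a,hash_b the two results' plan hashes.
#' @return a `voicebdi_fold_diffs`.
#' @export
paired_fold_diffs <- function(model_a, model_b, metric, d,
                              hash_a, hash_b) {
  if (!identical(hash_a, hash_b)) {
    stop("fold plans differ between the compared models", call. = FALSE)
  }
  structure(list(model_a = model_a, model_b = model_b, metric = metric,
                 d = as.numeric(d), plan_hash = hash_a),
            class = "voicebdi_fold_diffs")
}

#' Compare two benchmark results on a metric
#'
#' @param res_a,res_b `voicebdi_benchmark_result`s on the same plan.
#' @param metric "mae" or "r2".
#' @return a `voicebdi_fold_diffs` (a minus b).
#' @export
fold_diffs <- function(res_a, res_b, metric = c("mae", "r2")) {
  metric <- match.arg(metric)
  fa <- if (metric == "mae") res_a$fold_mae else res_a$fold_r2
  fb <- if (metric == "mae") res_b$fold_mae else res_b$fold_r2
  paired_fold_diffs(res_a$model, res_b$model, metric, fa - fb,
                    res_a$plan_hash, res_b$plan_hash)
}

#' Paired sign-flip permutation test over folds
#'
#' Statistic = mean(d). Signs are flipped exhaustively when 2^n <= 4096
#' (n = 5 folds gives all 32 patterns, an exact small-sample null);
#' otherwise sampled with an add-one correction. Two-sided p; percentile
#' bootstrap CI on the mean difference.
#'
#' @param diffs a `voicebdi_fold_diffs` or plain numeric vector.
#' @param n_perm sampled permutations when not exhaustive.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed seed for sampling and bootstrap.
#' @return list with `p`, `mean_diff`, `ci` (2-vector), `exhaustive`.
#' @export
signflip_test <- function(diffs, n_perm = 1000, n_boot = 2000, seed = 1L) {
  d <- if (inherits(diffs, "voicebdi_fold_diffs")) diffs$d else
    as.numeric(diffs)
  n <- length(d)
  stopifnot(n >= 2)
  obs <- mean(d)
  if (all(d == 0)) {
    return(list(p = 1, mean_diff = 0, ci = c(0, 0), exhaustive = TRUE))
  }
  if (2^n <= 4096) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_means <- as.numeric(signs %*% d) / n
    p <- mean(abs(null_means) >= abs(obs) - 1e-12)
    exhaustive <- TRUE
  } else {
    null_means <- with_seed(substream_seed(seed, "signflip"), {
      vapply(seq_len(n_perm), function(i) {
        mean(d * sample(c(-1, 1), n, replace = TRUE))
      }, numeric(1))
    })
    p <- (1 + sum(abs(null_means) >= abs(obs) - 1e-12)) / (1 + n_perm)
    exhaustive <- FALSE
  }
  ci <- with_seed(substream_seed(seed, "signflip_boot"), {
    bm <- vapply(seq_len(n_boot), function(i) {
      mean(d[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  })
  list(p = p, mean_diff = obs, ci = ci, exhaustive = exhaustive)
}

#' Label-shuffle permutation test for a benchmark model
#'
#' Re-runs the pipeline on permuted targets and compares the observed metric
#' with the permutation null, `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#' The default unit is the participant: whole per-participant target blocks
#' are swapped between participants of equal diary count (preserving the
#' grouping structure the CV protects); `unit = "diary"` shuffles at the
#' diary level. Permutation re-runs use the reduced `space` budget.
#'
#' @param x modality matrix (rows aligned to targets).
#' @param targets numeric BDI sums.
#' @param participant_ids grouping variable.
#' @param plan fold plan (shared with the observed fit).
#' @param space reduced [search_space()] for the re-runs (budget 5 by
#'   default; 0 = fixed configuration).
#' @param n_perm permutations (>= 20).
#' @param metric "r2" (larger = stronger) or "mae".
#' @param unit permutation unit.
#' @param seed seed.
#' @param observed optional precomputed `voicebdi_benchmark_result` on the
#'   same plan and space.
#' @return list with `p`, `observed`, `null` (vector of permuted metrics).
#' @export
label_shuffle_test <- function(x, targets, participant_ids, plan,
                               space = search_space(budget = 5),
                               n_perm = 1000, metric = c("r2", "mae"),
                               unit = c("participant", "diary"), seed = 1L,
                               observed = NULL) {
  metric <- match.arg(metric)
  unit <- match.arg(unit)
  if (n_perm < 20) stop("n_perm must be >= 20", call. = FALSE)
  stat_of <- function(res) {
    if (metric == "r2") mean(res$fold_r2) else -mean(res$fold_mae)
  }
  if (is.null(observed)) {
    observed <- fit_eval_single(x, targets, participant_ids, plan, space,
                                model_name = "observed")
  }
  obs <- stat_of(observed)
  pid <- as.character(participant_ids)
  null_stats <- with_seed(substream_seed(seed, "label_shuffle"), {
    vapply(seq_len(n_perm), function(i) {
      yp <- permute_targets(targets, pid, unit)
      stat_of(fit_eval_single(x, yp, pid, plan, space,
                              model_name = "perm",
                              seed = substream_seed(seed, paste0("p", i))))
    }, numeric(1))
  })
  p <- (1 + sum(null_stats >= obs - 1e-12)) / (1 + n_perm)
  list(p = p, observed = obs, null = null_stats, metric = metric,
       unit = unit)
}

# Swap whole per-participant target blocks between participants with equal
# diary counts; participants with a unique count keep their block.
permute_targets <- function(targets, pid, unit) {
  if (unit == "diary") return(sample(targets))
  idx_by_pid <- split(seq_along(targets), pid)
  counts <- lengths(idx_by_pid)
  out <- targets
  for (ct in unique(counts)) {
    ps <- names(counts)[counts == ct]
    if (length(ps) < 2) next
    perm <- sample(ps)
    for (j in seq_along(ps)) {
      out[idx_by_pid[[ps[j]]]] <- targets[idx_by_pid[[perm[j]]]]
    }
  }
  out
}

#' Effect sizes
#'
#' `cohen_dz` is the paired effect size mean(d)/sd(d); `cliffs_delta` the
#' dominance statistic; `cohens_f2` the incremental-variance effect
#' (r2_full - r2_reduced) / (1 - r2_full).
#'
#' @param d numeric vector of paired differences.
#' @return `cohen_dz`: list(dz, degenerate).
#' @export
cohen_dz <- function(d) {
  s <- stats::sd(d)
  if (s == 0) {
    return(list(dz = sign(mean(d)) * Inf, degenerate = TRUE))
  }
  list(dz = mean(d) / s, degenerate = FALSE)
}

#' @rdname cohen_dz
#' @param a,b numeric vectors.
#' @export
cliffs_delta <- function(a, b) {
  gt <- sum(outer(a, b, `>`))
  lt <- sum(outer(a, b, `<`))
  (gt - lt) / (length(a) * length(b))
}

#' @rdname cohen_dz
#' @param r2_full,r2_reduced coefficients of determination.
#' @export
cohens_f2 <- function(r2_full, r2_reduced) {
  if (r2_full >= 1) {
    return(list(f2 = NA_real_, degenerate = TRUE))
  }
  list(f2 = (r2_full - r2_reduced) / (1 - r2_full), degenerate = FALSE)
}

#' Holm-Bonferroni step-down procedure
#'
#' @param p_values raw p-values in [0, 1].
#' @param alpha familywise error level.
#' @return list with `adjusted` (monotone adjusted p) and `reject` mask.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p_values, method = "holm")
  list(adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Spearman correlation with a Fisher-z confidence interval
#'
#' Average ranks for ties; CI = tanh(atanh(rho) +/- 1.96/sqrt(n-3)).
#' |rho| at 1 is clamped with a degenerate-CI flag; constant input is
#' flagged undefined.
#'
#' @param x,y numeric vectors (n >= 4).
#' @return list with `rho`, `ci`, `n`, `degenerate`, `undefined`.
#' @export
spearman_fisher_ci <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_), n = length(x),
                degenerate = FALSE, undefined = TRUE))
  }
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  if (abs(rho) >= 1 - 1e-12) {
    rho <- sign(rho)
    return(list(rho = rho, ci = c(rho, rho), n = n, degenerate = TRUE,
                undefined = FALSE))
  }
  z <- atanh(rho)
  hw <- 1.96 / sqrt(n - 3)
  list(rho = rho, ci = tanh(c(z - hw, z + hw)), n = n,
       degenerate = FALSE, undefined = FALSE)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H with the chi-squared approximation (df = k - 1).
#'
#' @param groups list of numeric vectors (each non-empty, >= 2 groups).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) > 0))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Percentile bootstrap CI of a statistic
#'
#' @param x data vector (or matrix resampled by row).
#' @param stat function of the resample.
#' @param n_boot resamples.
#' @param seed seed.
#' @param probs CI probabilities.
#' @return numeric 2-vector.
#' @export
boot_ci <- function(x, stat, n_boot = 2000, seed = 1L,
                    probs = c(0.025, 0.975)) {
  n <- if (is.matrix(x) || is.data.frame(x)) nrow(x) else length(x)
  vals <- with_seed(substream_seed(seed, "boot"), {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (is.matrix(x) || is.data.frame(x)) {
        stat(x[idx, , drop = FALSE])
      } else {
        stat(x[idx])
      }
    }, numeric(1))
  })
  stats::quantile(vals, probs, names = FALSE, na.rm = TRUE)
}

#' Head-to-head comparison report between two benchmark results
#'
#' Sign-flip p, mean paired difference with bootstrap CI, Cohen's d_z
#' (Cliff's delta additionally for MAE), and Cohen's f2 for R2 contrasts.
#'
#' @param res_a,res_b `voicebdi_benchmark_result`s on the same plan.
#' @param seed seed.
#' @return one-row data.frame per metric, rbound.
#' @export
compare_models <- function(res_a, res_b, seed = 1L) {
  rows <- lapply(c("mae", "r2"), function(metric) {
    fd <- fold_diffs(res_a, res_b, metric)
    st <- signflip_test(fd, seed = substream_seed(seed, metric))
    dz <- cohen_dz(fd$d)
    row <- data.frame(model_a = res_a$model, model_b = res_b$model,
                      metric = metric, mean_diff = st$mean_diff,
                      ci_lo = st$ci[1], ci_hi = st$ci[2], p = st$p,
                      dz = dz$dz, cliffs_delta = NA_real_, f2 = NA_real_,
                      stringsAsFactors = FALSE)
    if (metric == "mae") {
      row$cliffs_delta <- cliffs_delta(res_a$fold_mae, res_b$fold_mae)
    } else {
      row$f2 <- cohens_f2(max(res_a$r2_mean, res_b$r2_mean),
                          min(res_a$r2_mean, res_b$r2_mean))$f2
    }
    row
  })
  do.call(rbind, rows)
}
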