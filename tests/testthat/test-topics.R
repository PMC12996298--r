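# Three well-separated synthetic blobs in embedding space.
blob_matrix <- function(n_per = 40, dim = 16, sep = 8, seed = 3) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(3 * dim), 3, dim)
    centers <- sep * centers / sqrt(rowSums(centers^2))
    x <- do.call(rbind, lapply(1:3, function(k) {
      sweep(matrix(rnorm(n_per * dim, 0, 0.5), n_per, dim), 2,
            centers[k, ], `+`)
    }))
    rownames(x) <- sprintf("D%03d", seq_len(3 * n_per))
    list(x = x, truth = rep(1:3, each = n_per))
  })
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(choose(v, 2))
  s_ab <- comb2(as.vector(tab))
  s_a <- comb2(rowSums(tab))
  s_b <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- s_a * s_b / n2
  (s_ab - expected) / ((s_a + s_b) / 2 - expected)
}

test_that("well-separated blobs are recovered almost perfectly", {
  bl <- blob_matrix()
  cl <- cluster_diaries(bl$x, min_cluster_size = 10)
  lab <- reassign_outliers(cl$labels, bl$x)
  expect_gte(length(unique(lab)), 3)
  expect_gt(adjusted_rand(lab, bl$truth), 0.9)
  # determinism
  cl2 <- cluster_diaries(bl$x, min_cluster_size = 10)
  expect_identical(cl$labels, cl2$labels)
})

test_that("a single blob yields at most one non-noise cluster", {
  withr::with_seed(5, {
    x <- matrix(rnorm(60 * 8), 60, 8)
    rownames(x) <- sprintf("D%02d", 1:60)
    cl <- cluster_diaries(x, min_cluster_size = 10)
    expect_lte(length(setdiff(unique(cl$labels), -1L)), 1)
  })
  expect_error(cluster_diaries(matrix(0, 40, 4,
                                      dimnames = list(1:40, NULL))),
               "degenerate")
  expect_error(cluster_diaries(matrix(rnorm(40), 10, 4)), "at least 30")
})

test_that("outlier reassignment honours nearest centroids and ties", {
  x <- rbind(matrix(rep(c(1, 0), each = 5), 5, 2),
             matrix(rep(c(0, 1), each = 5), 5, 2),
             c(0.7, 0.7))
  labels <- c(rep(1L, 5), rep(2L, 5), -1L)
  out <- reassign_outliers(labels, x)
  expect_false(any(out == -1L))
  expect_equal(out[1:10], labels[1:10]) # non-noise untouched
  expect_equal(out[11], 1L)             # equidistant -> lower id wins
  expect_equal(reassign_outliers(labels[1:10], x[1:10, ]), labels[1:10])
  expect_error(reassign_outliers(rep(-1L, 3), x[1:3, ]), "soft_assign")
  # reassigned point is no farther from its centroid than from any other
  bl <- blob_matrix(seed = 7)
  cl <- cluster_diaries(bl$x, min_cluster_size = 10)
  if (any(cl$labels == -1L)) {
    out2 <- reassign_outliers(cl$labels, bl$x)
    cen <- voicebdi:::cluster_centroids(bl$x, cl$labels)
    for (i in which(cl$labels == -1L)) {
      d <- voicebdi:::cosine_dist(bl$x[i, , drop = FALSE], cen)
      expect_equal(as.character(out2[i]),
                   rownames(cen)[which.min(d)])
    }
  }
})

test_that("soft assignment is a valid row-stochastic softmax", {
  x <- rbind(c(1, 0), c(0, 1), c(sqrt(0.5), sqrt(0.5)))
  centroids <- rbind(`1` = c(1, 0), `2` = c(0, 1))
  sa <- soft_assign(x, centroids, temperature = 0.05)
  expect_equal(rowSums(sa$probabilities), rep(1, 3))
  expect_gt(sa$probabilities[1, "1"], 0.99) # at-centroid, low temperature
  expect_equal(unname(sa$probabilities[3, ]), c(0.5, 0.5)) # equidistant
  expect_equal(sa$labels[1:2], c(1L, 2L))
  expect_error(soft_assign(x, centroids, temperature = 0), "> 0")
  withr::with_seed(9, {
    xr <- matrix(rnorm(50 * 2), 50, 2)
    sar <- soft_assign(xr, centroids)
    expect_equal(rowSums(sar$probabilities), rep(1, 50))
  })
})

test_that("cTF-IDF ranks exclusive terms above uniform ones", {
  texts <- list(c("uniq1", "shared", "shared"),
                c("uniq1", "shared"),
                c("uniq2", "shared"),
                c("uniq2", "shared", "shared"))
  labels <- c(1, 1, 2, 2)
  kw <- ctfidf_keywords(labels, texts, top_n = 2)
  expect_equal(kw[["1"]][1], "uniq1")
  expect_equal(kw[["2"]][1], "uniq2")
  # hand-computed weight: W(t,c) = tf * log(1 + A / f)
  tf_uniq1 <- 2; f_uniq1 <- 2; a <- (5 + 5) / 2
  expect_equal(tf_uniq1 * log(1 + a / f_uniq1) >
                 3 * log(1 + a / 7), TRUE) # shared in class 1 has tf 3, f 7
  # single theme degenerates to tf ordering
  kw1 <- ctfidf_keywords(rep(1, 4), texts, top_n = 3)
  expect_equal(kw1[["1"]][1], "shared")
  expect_error(ctfidf_keywords(1, list(character())), "empty vocabulary")
})

test_that("representative documents are the top members by probability", {
  p <- matrix(c(0.9, 0.1,
                0.8, 0.2,
                0.3, 0.7,
                0.6, 0.4), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("1", "2")))
  ids <- c("a", "b", "c", "d")
  labels <- c(1, 1, 2, 1)
  reps <- representative_docs(p, labels, ids, top = 2)
  expect_equal(reps[["1"]], c("a", "b"))
  expect_equal(reps[["2"]], "c") # only member returned even if fewer than top
  # ties break by diary id
  p2 <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 4, 2,
               dimnames = list(NULL, c("1", "2")))
  reps2 <- representative_docs(p2, c(1, 1, 1, 1), c("d", "c", "b", "a"),
                               top = 2)
  expect_equal(reps2[["1"]], c("a", "b"))
})

test_that("merging split clusters recovers the coarse partition", {
  # two true themes, each split into two nearby sub-blobs
  withr::with_seed(11, {
    dim <- 12
    base <- matrix(rnorm(2 * dim), 2, dim)
    base <- 10 * base / sqrt(rowSums(base^2))
    sub <- rbind(base[1, ] + rnorm(dim, 0, 0.8),
                 base[1, ] - rnorm(dim, 0, 0.8),
                 base[2, ] + rnorm(dim, 0, 0.8),
                 base[2, ] - rnorm(dim, 0, 0.8))
    x <- do.call(rbind, lapply(1:4, function(k) {
      sweep(matrix(rnorm(30 * dim, 0, 0.3), 30, dim), 2, sub[k, ], `+`)
    }))
    rownames(x) <- sprintf("D%03d", 1:120)
    truth <- rep(c(1, 1, 2, 2), each = 30)
    labels <- rep(1:4, each = 30)
    sa <- soft_assign(x, voicebdi:::cluster_centroids(x, labels))
    merged <- merge_to_themes(labels, x, sa$probabilities, target_k = 2)
    expect_gt(adjusted_rand(merged$labels, truth), 0.95)
    expect_equal(unname(rowSums(merged$probabilities)), rep(1, 120),
                 tolerance = 1e-9)
    # already at target: identity map
    m2 <- merge_to_themes(truth, x, sa$probabilities[, 1:2] /
                            rowSums(sa$probabilities[, 1:2]), target_k = 2)
    expect_equal(unname(m2$theme_map), c(1, 2))
    expect_warning(merge_to_themes(truth, x,
                                   sa$probabilities[, 1:2] /
                                     rowSums(sa$probabilities[, 1:2]),
                                   target_k = 3), "fewer raw clusters")
  })
})

test_that("topic-BDI summary orders themes by mean severity", {
  co <- generate_cohort(cohort_config(n_participants = 60, seed = 83,
                                      adherence_log_mean = log(3),
                                      adherence_log_sd = 0.5,
                                      tokens_per_diary = 150))
  mt <- modeling_table(co)
  pr <- embedding_provider("t", dim = 256, seed = 5, beta = 0,
                           noise_sd = 0.05,
                           block_weights = c(3, 0.3, 0.3, 0.2))
  x <- build_modality_matrix(co, pr, mt$diary_id)
  tp <- fit_topics(x, normalized_corpus(co, mt$diary_id), target_k = 6,
                   min_cluster_size = 8)
  expect_false(any(tp$final_labels == -1))
  expect_equal(unname(rowSums(tp$probabilities)), rep(1, nrow(mt)),
               tolerance = 1e-9)
  ts <- topic_bdi_summary(tp, mt)
  expect_equal(sum(ts$table$n), nrow(mt))
  expect_true(all(diff(ts$table$bdi_mean) <= 1e-12))
  expect_true(ts$kruskal$H >= 0)
})

test_that("topic-item correlations flag a planted link and control FWER", {
  withr::with_seed(17, {
    n <- 300
    items <- matrix(sample(0:3, n * 21, replace = TRUE), n, 21)
    # theme probability driven by item 4
    p1 <- as.numeric(plogis(1.2 * scale(items[, 4]) + rnorm(n, 0, 0.8)))
    probs <- cbind(`1` = p1, `2` = 1 - p1)
    probs <- probs / rowSums(probs)
    res <- topic_item_correlations(probs, items)
    cell <- res[res$theme == "1" & res$item == 4, ]
    expect_true(cell$significant)
    expect_gt(cell$rho, 0.2)
    # constant probability column -> undefined flags
    probs0 <- cbind(`1` = rep(0.5, n), `2` = rep(0.5, n))
    res0 <- topic_item_correlations(probs0, items)
    expect_true(all(res0$undefined))
  })
})
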