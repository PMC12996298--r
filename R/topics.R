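#' @name topics
#' @title Embedding-space topics: clustering, keywords, symptom links
#'
#' @description
#' The interpretability layer. Diaries are clustered in embedding space
#' (PCA reduction on L2-normalised vectors, then density-based clustering
#' with a noise label), noise points are reassigned to the nearest centroid,
#' per-diary topic probabilities come from a centroid-distance softmax,
#' clusters are consolidated into a small theme set by agglomerative merging
#' of centroids, themes are labelled by class-based TF-IDF keywords and
#' representative diaries, and topic-symptom associations use Spearman
#' correlations with Holm control within each topic's 21 BDI items.
NULL

# Hand-rolled DBSCAN on a precomputed distance matrix: core points have at
# least min_pts neighbours within eps; clusters are the connected components
# of core points, with border points attached and noise labelled -1.
dbscan_labels <- function(d, eps, min_pts) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == -1L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Cluster diaries in embedding space
#'
#' Reduces L2-normalised embeddings to `n_dims` principal components, then
#' runs density-based clustering (minimum cluster size
#' `max(15, n/100)` by default) in the reduced space. A noise label (-1) is
#' permitted at this stage. Deterministic given the inputs.
#'
#' @param x modality matrix (diaries x dim), rownames = diary ids.
#' @param n_dims reduced dimensionality.
#' @param min_cluster_size minimum cluster size (density threshold).
#' @param eps_quantile neighbourhood radius quantile of the k-nearest
#'   distances used to set the density radius.
#' @return list with `labels` (integer, -1 = noise), `coords`, `diary_ids`.
#' @export
cluster_diaries <- function(x, n_dims = 5,
                            min_cluster_size = max(15, nrow(x) %/% 100),
                            eps_quantile = 0.90) {
  if (nrow(x) < 30) stop("need at least 30 diaries", call. = FALSE)
  xs <- l2_normalize_rows(as.matrix(x))
  if (all(apply(xs, 2, stats::sd) == 0)) {
    stop("degenerate embedding variance", call. = FALSE)
  }
  k <- min(n_dims, ncol(xs), nrow(xs) - 1L)
  pc <- stats::prcomp(xs, center = TRUE, scale. = FALSE, rank. = k)
  coords <- pc$x
  d <- as.matrix(stats::dist(coords))
  kth <- apply(d, 1, function(r) sort(r)[min_cluster_size + 1L])
  eps <- stats::quantile(kth, eps_quantile, names = FALSE)
  labels <- dbscan_labels(d, eps, min_cluster_size)
  list(labels = labels, coords = coords,
       diary_ids = rownames(x), eps = eps,
       min_cluster_size = min_cluster_size)
}

cluster_centroids <- function(x, labels) {
  ids <- sort(unique(labels[labels != -1L]))
  if (length(ids) == 0) stop("no non-noise cluster", call. = FALSE)
  cen <- t(vapply(ids, function(c) colMeans(x[labels == c, , drop = FALSE]),
                  numeric(ncol(x))))
  rownames(cen) <- ids
  cen
}

#' Reassign noise points to the nearest cluster
#'
#' Each noise diary takes the cluster whose centroid is nearest in cosine
#' distance; equidistant ties resolve to the lower cluster id. Non-noise
#' labels are untouched.
#'
#' @param labels integer labels with -1 noise.
#' @param x embedding matrix used for clustering.
#' @return integer labels without noise.
#' @export
reassign_outliers <- function(labels, x) {
  if (all(labels == -1L)) {
    stop("all points are noise; use soft_assign as fallback", call. = FALSE)
  }
  if (!any(labels == -1L)) return(labels)
  cen <- cluster_centroids(x, labels)
  noise <- which(labels == -1L)
  d <- cosine_dist(as.matrix(x)[noise, , drop = FALSE], cen)
  pick <- apply(d, 1, function(r) which(r <= min(r) + 1e-12)[1])
  labels[noise] <- as.integer(rownames(cen))[pick]
  labels
}

#' Soft topic assignment via a centroid-distance softmax
#'
#' probabilities = softmax(-distance / temperature) per diary; the dominant
#' label is the argmax. Default temperature is the median diary-centroid
#' distance.
#'
#' @param x embedding matrix.
#' @param centroids cluster centroid matrix (rows = topics).
#' @param temperature softmax temperature (> 0).
#' @return list with `probabilities` (row-stochastic) and `labels`.
#' @export
soft_assign <- function(x, centroids, temperature = NULL) {
  d <- cosine_dist(as.matrix(x), centroids)
  if (is.null(temperature)) temperature <- stats::median(d)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  l <- -d / temperature
  l <- l - apply(l, 1, max)
  p <- exp(l)
  p <- p / rowSums(p)
  labels <- as.integer(rownames(centroids))[apply(p, 1, which.max)]
  colnames(p) <- rownames(centroids)
  list(probabilities = p, labels = labels)
}

#' Class-based TF-IDF keywords per theme
#'
#' For theme c and term t: W(t, c) = tf(t, c) * log(1 + A / f(t)), where
#' tf is the term frequency in the concatenated class document, f the total
#' corpus frequency, and A the average term count per class.
#'
#' @param final_labels theme label per document.
#' @param texts list of normalised token vectors (same order).
#' @param top_n keywords per theme.
#' @return named list of ranked keyword character vectors.
#' @export
ctfidf_keywords <- function(final_labels, texts, top_n = 10) {
  stopifnot(length(final_labels) == length(texts))
  vocab <- sort(unique(unlist(texts)))
  if (length(vocab) == 0) stop("empty vocabulary", call. = FALSE)
  classes <- sort(unique(final_labels))
  tf <- matrix(0, length(classes), length(vocab),
               dimnames = list(classes, vocab))
  for (i in seq_along(texts)) {
    if (length(texts[[i]]) == 0) next
    tt <- table(texts[[i]])
    ci <- as.character(final_labels[i])
    tf[ci, names(tt)] <- tf[ci, names(tt)] + as.numeric(tt)
  }
  f <- colSums(tf)
  a <- mean(rowSums(tf))
  w <- sweep(tf, 2, log(1 + a / pmax(f, 1e-12)), `*`)
  out <- lapply(classes, function(cl) {
    ord <- order(w[as.character(cl), ], decreasing = TRUE)
    head_terms <- vocab[ord]
    head_terms[w[as.character(cl), ord] > 0][seq_len(
      min(top_n, sum(w[as.character(cl), ] > 0)))]
  })
  names(out) <- classes
  out
}

#' Representative diaries per theme
#'
#' The top member diaries of each theme by that theme's probability;
#' deterministic tie-break by diary id.
#'
#' @param probabilities row-stochastic matrix (diaries x topics), colnames =
#'   topic ids.
#' @param final_labels theme label per diary.
#' @param diary_ids diary ids (row order).
#' @param top number of representatives.
#' @return named list of diary-id vectors.
#' @export
representative_docs <- function(probabilities, final_labels, diary_ids,
                                top = 10) {
  classes <- colnames(probabilities)
  out <- lapply(classes, function(cl) {
    member <- which(as.character(final_labels) == cl)
    p <- probabilities[member, cl]
    ord <- member[order(-p, diary_ids[member])]
    diary_ids[utils::head(ord, top)]
  })
  names(out) <- classes
  out
}

#' Merge raw clusters into a consolidated theme set
#'
#' Agglomerative merging of cluster centroids (cosine distance, average
#' linkage) until `target_k` themes remain; probabilities are aggregated by
#' summation over merged clusters.
#'
#' @param labels raw cluster labels (no noise).
#' @param x embedding matrix.
#' @param probabilities raw row-stochastic probabilities (colnames = raw
#'   cluster ids).
#' @param target_k consolidated theme count.
#' @return list with `theme_map` (raw id -> theme id), `labels`,
#'   `probabilities` (aggregated), `centroids` (theme centroids).
#' @export
merge_to_themes <- function(labels, x, probabilities, target_k = 6) {
  cen <- cluster_centroids(x, labels)
  raw_ids <- as.integer(rownames(cen))
  if (length(raw_ids) <= target_k) {
    if (length(raw_ids) < target_k) {
      warning("fewer raw clusters than target_k; themes = raw clusters")
    }
    map <- stats::setNames(seq_along(raw_ids), raw_ids)
  } else {
    d <- stats::as.dist(cosine_dist(cen, cen))
    hc <- stats::hclust(d, method = "average")
    map <- stats::setNames(stats::cutree(hc, k = target_k), raw_ids)
  }
  new_labels <- as.integer(map[as.character(labels)])
  themes <- sort(unique(map))
  probs <- vapply(themes, function(th) {
    cols <- names(map)[map == th]
    rowSums(probabilities[, cols, drop = FALSE])
  }, numeric(nrow(probabilities)))
  colnames(probs) <- themes
  cents <- t(vapply(themes, function(th) {
    colMeans(x[new_labels == th, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(cents) <- themes
  list(theme_map = map, labels = new_labels, probabilities = probs,
       centroids = cents)
}

#' Fit the full topic model for a cohort
#'
#' Clustering, outlier reassignment (with the soft-assignment fallback when
#' everything is noise), consolidation to `target_k` themes, soft
#' probabilities, keywords, and representatives.
#'
#' @param x modality matrix over paired diaries (rownames = diary ids).
#' @param texts named list of normalised token vectors (same diary ids).
#' @param target_k consolidated theme count.
#' @param n_dims,min_cluster_size,eps_quantile passed to [cluster_diaries()].
#' @param temperature softmax temperature (NULL = median distance).
#' @return a `voicebdi_topics` list.
#' @export
fit_topics <- function(x, texts, target_k = 6, n_dims = 5,
                       min_cluster_size = max(15, nrow(x) %/% 100),
                       eps_quantile = 0.90, temperature = NULL) {
  cl <- cluster_diaries(x, n_dims, min_cluster_size, eps_quantile)
  raw <- cl$labels
  if (all(raw == -1L)) {
    # degenerate single-density case: treat everything as one cluster
    raw <- rep(1L, length(raw))
  } else {
    raw <- reassign_outliers(raw, x)
  }
  cen <- cluster_centroids(x, raw)
  sa <- soft_assign(x, cen, temperature)
  merged <- merge_to_themes(raw, x, sa$probabilities, target_k)
  theme_sa <- soft_assign(x, merged$centroids, temperature)
  texts <- texts[cl$diary_ids]
  keywords <- ctfidf_keywords(merged$labels, texts)
  reps <- representative_docs(merged$probabilities, merged$labels,
                              cl$diary_ids)
  structure(list(diary_ids = cl$diary_ids,
                 raw_labels = cl$labels,
                 final_labels = merged$labels,
                 probabilities = merged$probabilities,
                 theme_map = merged$theme_map,
                 centroids = merged$centroids,
                 keywords = keywords,
                 representatives = reps,
                 coords = cl$coords),
            class = "voicebdi_topics")
}

#' Per-theme BDI summary with the Kruskal-Wallis omnibus
#'
#' Themes ordered by mean BDI descending; n = diaries, N = unique
#' participants.
#'
#' @param topics a `voicebdi_topics`.
#' @param mt modelling table (diary_id, participant_id, bdi_sum).
#' @return list with `table` and `kruskal`.
#' @export
topic_bdi_summary <- function(topics, mt) {
  idx <- match(topics$diary_ids, mt$diary_id)
  stopifnot(!anyNA(idx))
  df <- data.frame(theme = topics$final_labels,
                   participant_id = mt$participant_id[idx],
                   bdi = mt$bdi_sum[idx])
  tab <- do.call(rbind, lapply(split(df, df$theme), function(d) {
    data.frame(theme = d$theme[1], n = nrow(d),
               n_participants = length(unique(d$participant_id)),
               bdi_mean = mean(d$bdi), bdi_sd = stats::sd(d$bdi))
  }))
  tab <- tab[order(-tab$bdi_mean), ]
  rownames(tab) <- NULL
  kw <- if (length(unique(df$theme)) >= 2) {
    kruskal_wallis(split(df$bdi, df$theme))
  } else {
    # degenerate single-theme solution: no between-theme contrast exists
    list(H = NA_real_, df = 0L, p = NA_real_)
  }
  list(table = tab, kruskal = kw)
}

#' Topic-probability x BDI-item Spearman correlations
#'
#' One Spearman rho (with Fisher-z CI) per theme x item cell; Holm control
#' within each theme across the 21 items.
#'
#' @param probabilities row-stochastic theme probabilities per diary.
#' @param items matrix of the 21 BDI item scores per diary (same row order).
#' @param alpha familywise level for the Holm mask.
#' @return data.frame with theme, item, rho, ci, raw and adjusted p,
#'   significance mask.
#' @export
topic_item_correlations <- function(probabilities, items, alpha = 0.05) {
  stopifnot(nrow(probabilities) == nrow(items), ncol(items) == 21)
  themes <- colnames(probabilities)
  out <- list()
  for (th in themes) {
    p <- probabilities[, th]
    cells <- lapply(seq_len(21), function(j) {
      sp <- spearman_fisher_ci(p, items[, j])
      pr <- if (sp$undefined || sp$degenerate) {
        if (sp$undefined) NA_real_ else 0
      } else {
        n <- sp$n
        z <- atanh(sp$rho) * sqrt(n - 3)
        2 * stats::pnorm(-abs(z))
      }
      data.frame(theme = th, item = j, rho = sp$rho,
                 ci_lo = sp$ci[1], ci_hi = sp$ci[2], p = pr,
                 undefined = sp$undefined, stringsAsFactors = FALSE)
    })
    cells <- do.call(rbind, cells)
    hb <- holm_bonferroni(cells$p, alpha)
    cells$p_adj <- hb$adjusted
    cells$significant <- hb$reject
    out[[th]] <- cells
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
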