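#' @name embeddings
#' @title Embedding provider contract and the synthetic hashing provider
#'
#' @description
#' A provider maps a verbatim (un-normalised) token sequence to one
#' fixed-length vector per diary. The synthetic provider uses signed feature
#' hashing over four blocks — unigram surfaces, order-sensitive adjacent
#' bigrams, word-final character trigrams (inflection carriers), and
#' function-word patterns — plus a planted severity direction and isotropic
#' noise, so perturbation and benchmark experiments are runnable at desk
#' scale with controllable signal.
NULL

#' Construct a synthetic embedding provider
#'
#' The embedded vector is `A phi(tokens) + beta * s * u + eps`, where `phi`
#' hashes the four feature families into disjoint blocks of the embedding
#' (each block L2-normalised then scaled by its block weight), `u` is a fixed
#' seeded unit direction, `s` the diary's latent severity, and `eps`
#' isotropic Gaussian noise drawn from a per-diary sub-stream (so rows are a
#' pure function of diary identity, never of row order).
#'
#' `type = "speaker_confound"` replaces the per-diary severity term with a
#' per-speaker fingerprint plus a weak direction carrying only the speaker's
#' mean severity — a construction with no within-person signal, used to
#' demonstrate what ungrouped cross-validation would inflate.
#'
#' @param name modality name.
#' @param dim embedding dimensionality (>= 8; rounded up to a multiple of 4).
#' @param seed provider seed (feature-hash salt, direction, noise streams).
#' @param beta severity signal weight (overridden if `target_r2` is set at
#'   matrix-build time, where noise is calibrated instead).
#' @param noise_sd isotropic noise SD.
#' @param target_r2 optional target fraction of BDI variance encoded along
#'   the severity direction; calibrated empirically per cohort when building
#'   a matrix.
#' @param block_weights length-4 weights for the unigram / bigram / trigram /
#'   function-pattern blocks.
#' @param type "diary" (severity of the diary) or "speaker_confound".
#' @param confound_scale fingerprint scale for "speaker_confound".
#' @return a `voicebdi_provider`.
#' @export
embedding_provider <- function(name, dim = 256, seed = 1L,
                               beta = 1, noise_sd = 1,
                               target_r2 = NULL,
                               block_weights = c(1, 1, 1, 1),
                               type = c("diary", "speaker_confound"),
                               confound_scale = 2) {
  type <- match.arg(type)
  if (dim < 8) stop("embedding dim must be >= 8", call. = FALSE)
  dim <- as.integer(4 * ceiling(dim / 4))
  u <- with_seed(substream_seed(seed, "direction"), stats::rnorm(dim))
  u <- u / sqrt(sum(u^2))
  structure(list(name = name, dim = dim, seed = as.integer(seed),
                 beta = beta, noise_sd = noise_sd, target_r2 = target_r2,
                 block_weights = block_weights, type = type,
                 confound_scale = confound_scale, u = u),
            class = "voicebdi_provider")
}

# Signed-hash a character vector of features into a length-`size` block.
hash_block <- function(feats, size, salt) {
  v <- numeric(size)
  if (length(feats) == 0) return(v)
  h <- hash_strings(paste0(salt, "\r", feats))
  idx <- (h %/% 2) %% size + 1
  sgn <- ifelse(h %% 2 == 0, 1, -1)
  for (j in seq_along(idx)) v[idx[j]] <- v[idx[j]] + sgn[j]
  v
}

# phi: hashed feature map over four disjoint blocks.
phi_features <- function(tokens, provider) {
  b <- provider$dim %/% 4L
  salt <- as.character(provider$seed)
  surf <- tokens$surface
  uni <- surf
  bi <- character()
  if (nrow(tokens) >= 2) {
    same <- tokens$sentence[-1] == tokens$sentence[-nrow(tokens)]
    if (any(same)) {
      bi <- paste(surf[-length(surf)][same], surf[-1][same], sep = "→")
    }
  }
  nc <- nchar(surf)
  tri <- substr(surf, pmax(1, nc - 2), nc)[nc >= 3]
  fn <- surf[tokens$role == "function"]
  fun_feats <- c(fn, if (length(fn) >= 2) {
    paste(fn[-length(fn)], fn[-1], sep = "+")
  })
  norm1 <- function(x) { n <- sqrt(sum(x^2)); if (n > 0) x / n else x }
  w <- provider$block_weights
  c(w[1] * norm1(hash_block(uni, b, paste0(salt, ":uni"))),
    w[2] * norm1(hash_block(bi, b, paste0(salt, ":bi"))),
    w[3] * norm1(hash_block(tri, b, paste0(salt, ":tri"))),
    w[4] * norm1(hash_block(fun_feats, b, paste0(salt, ":fun"))))
}

#' Embed one token sequence
#'
#' @param tokens data.frame with surface, lemma, role, sentence.
#' @param severity_signal the diary's latent severity (scalar).
#' @param provider a [embedding_provider()].
#' @param noise_key identifier keying the per-diary noise sub-stream
#'   (usually the diary id); NULL for noise-free output.
#' @param fingerprint_key identifier keying the speaker fingerprint for
#'   `type = "speaker_confound"` (usually the participant id).
#' @return numeric vector of length `provider$dim`.
#' @export
synthetic_embed <- function(tokens, severity_signal, provider,
                            noise_key = NULL, fingerprint_key = NULL) {
  v <- phi_features(tokens, provider)
  if (provider$type == "speaker_confound") {
    stopifnot(!is.null(fingerprint_key))
    fp <- with_seed(substream_seed(provider$seed,
                                   paste0("fp/", fingerprint_key)),
                    stats::rnorm(provider$dim))
    fp <- fp / sqrt(sum(fp^2))
    v <- v + provider$confound_scale * fp +
      provider$beta * severity_signal * provider$u
  } else {
    v <- v + provider$beta * severity_signal * provider$u
  }
  if (!is.null(noise_key) && provider$noise_sd > 0) {
    eps <- with_seed(substream_seed(provider$seed, paste0("eps/", noise_key)),
                     stats::rnorm(provider$dim, 0, provider$noise_sd))
    v <- v + eps
  }
  v
}

# Calibrate beta/noise so that the variance fraction of the BDI sum carried
# along u matches target_r2:  with beta = 1 and z = s + noise along u,
# R2 = cov(s, bdi)^2 / (var(z) var(bdi)), solved for the noise variance.
# Residual hash-block variance along u is measured and counted as noise.
calibrate_provider <- function(provider, severities, bdi_sums, hash_u_var) {
  r2 <- provider$target_r2
  if (is.null(r2)) return(provider)
  if (r2 <= 0) {
    provider$beta <- 0
    return(provider)
  }
  vs <- stats::var(severities)
  vb <- stats::var(bdi_sums)
  cv <- stats::cov(severities, bdi_sums)
  need <- cv^2 / (r2 * vb) - vs - hash_u_var
  if (need < 0) {
    warning("target_r2 above the attainable ceiling; using minimal noise")
    need <- 0
  }
  provider$beta <- 1
  provider$signal_noise_sd <- sqrt(need)
  provider
}

#' Build a modality matrix for a set of diaries
#'
#' Row order equals the input diary order; each row is a pure function of
#' the diary id, tokens and provider, so permuting the input permutes the
#' rows without changing any row. Provenance (provider name, seed, config
#' hash) is attached as attributes. When the provider carries `target_r2`,
#' the severity-direction noise is calibrated against the cohort's empirical
#' severity/BDI moments so the encoded variance fraction matches the target.
#'
#' @param cohort a `voicebdi_cohort`.
#' @param provider a [embedding_provider()].
#' @param diary_ids diaries to embed, in row order.
#' @return numeric matrix (diaries x dim) with rownames = diary ids.
#' @export
build_modality_matrix <- function(cohort, provider,
                                  diary_ids = cohort$diaries$diary_id) {
  dd <- cohort$diaries[match(diary_ids, cohort$diaries$diary_id), ]
  if (anyNA(dd$diary_id)) stop("unknown diary id in diary_ids", call. = FALSE)
  tok_split <- split(cohort$tokens, cohort$tokens$diary_id)
  empty_tok <- data.frame(surface = character(), lemma = character(),
                          role = character(), sentence = integer())
  phis <- t(vapply(diary_ids, function(id) {
    tk <- tok_split[[id]]
    if (is.null(tk)) tk <- empty_tok
    phi_features(tk, provider)
  }, numeric(provider$dim)))

  sev <- if (provider$type == "speaker_confound") {
    pm <- tapply(cohort$diaries$severity, cohort$diaries$participant_id, mean)
    as.numeric(pm[dd$participant_id])
  } else {
    dd$severity
  }

  if (!is.null(provider$target_r2)) {
    bdi_sums <- cohort_bdi_sums(cohort, diary_ids)
    keep <- !is.na(bdi_sums)
    hash_u_var <- stats::var(as.numeric(phis %*% provider$u))
    provider <- calibrate_provider(provider, dd$severity[keep],
                                   bdi_sums[keep], hash_u_var)
  }

  m <- phis + outer(provider$beta * sev, provider$u)
  if (provider$type == "speaker_confound") {
    up <- unique(dd$participant_id)
    fps <- vapply(up, function(p) {
      fp <- with_seed(substream_seed(provider$seed, paste0("fp/", p)),
                      stats::rnorm(provider$dim))
      fp / sqrt(sum(fp^2))
    }, numeric(provider$dim))
    m <- m + provider$confound_scale * t(fps[, match(dd$participant_id, up)])
  }
  if (provider$noise_sd > 0) {
    eps <- t(vapply(diary_ids, function(id) {
      with_seed(substream_seed(provider$seed, paste0("eps/", id)),
                stats::rnorm(provider$dim, 0, provider$noise_sd))
    }, numeric(provider$dim)))
    m <- m + eps
  }
  sn <- provider$signal_noise_sd
  if (!is.null(sn) && sn > 0) {
    zn <- vapply(diary_ids, function(id) {
      with_seed(substream_seed(provider$seed, paste0("zeps/", id)),
                stats::rnorm(1, 0, sn))
    }, numeric(1))
    m <- m + outer(zn, provider$u)
  }
  rownames(m) <- diary_ids
  attr(m, "modality") <- provider$name
  attr(m, "provider_seed") <- provider$seed
  attr(m, "config_hash") <- object_hash(unclass(provider)[
    setdiff(names(unclass(provider)), "u")])
  m
}

# Paired BDI sums in diary order (NA where unpaired).
cohort_bdi_sums <- function(cohort, diary_ids = cohort$diaries$diary_id) {
  paired <- pair_bdi(cohort$diaries, cohort$bdi)
  paired$bdi_sum[match(diary_ids, paired$diary_id)]
}
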