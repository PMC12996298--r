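#' @name synth_cohort
#' @title Synthetic voice-diary cohorts
#'
#' @description
#' Generates cohorts with the statistical structure a weekly voice-diary
#' depression-monitoring study assumes: two diagnostic groups (MDD and
#' healthy controls) with distinct BDI distributions, heavily right-skewed
#' per-participant adherence, within-person autocorrelated severity
#' trajectories, 21 BDI item scores consistent with the sum, and
#' theme-structured transcripts whose theme prevalence, word order and
#' inflection carry controllable severity signal. Everything downstream of
#' data collection is testable on these cohorts without any real data.
NULL

# Theme-specific content lexicons (lemmas). Theme 1 is the distress/care
# theme whose prevalence rises with severity under the default slopes.
.theme_lexicons <- list(
  distress = c("gefühl", "angst", "trauer", "wut", "schlaf", "müdigkeit",
               "klinik", "therapie", "tablette", "sorge", "grübeln", "hilfe"),
  weekly_state = c("woche", "befinden", "gut", "arbeit", "alltag", "garten",
                   "sport", "urlaub", "ruhig", "stabil", "zufrieden", "normal"),
  social = c("besuch", "freund", "familie", "reise", "treffen", "maske",
             "abstand", "regel", "kontakt", "gespräch", "feier", "nachbar"),
  procedure = c("aufnahme", "sprachprobe", "handy", "mikrofon", "laut",
                "erzählen", "frage", "zeit", "fertig", "anfang", "ende",
                "countdown"),
  activity = c("laufen", "schwimmen", "wandern", "knie", "schulter", "reha",
               "übung", "training", "fahrrad", "bewegung", "muskel",
               "spaziergang"),
  work_school = c("schule", "klasse", "unterricht", "zeugnis", "konferenz",
                  "gutachten", "kollege", "projekt", "termin", "büro",
                  "aufgabe", "prüfung")
)

# Fixed function-word inventory (also the stop-word list for normalisation).
.function_words <- c("ich", "und", "der", "die", "das", "ist", "war", "habe",
                     "nicht", "kein", "mir", "mich", "mein", "es", "in", "zu",
                     "mit", "auch", "aber", "so", "dann", "wieder", "sehr",
                     "ein", "eine", "bei", "auf", "äh", "ähm", "halt", "also")

.filler_words <- c("äh", "ähm", "halt", "also")
.negation_words <- c("nicht", "kein", "keine")
.first_person_words <- c("ich", "mir", "mich", "mein")

.proper_nouns <- c("Berlin", "Münster", "Marburg", "Anna", "Thomas",
                   "Jena", "Lisa", "Karlsruhe")
.numerals <- c("2021", "2022", "3", "7", "14", "60")

#' Accessors for the generator's fixed inventories
#'
#' @return character vectors of function words, filler words, negation words,
#'   first-person forms, and the named list of theme content lexicons.
#' @export
function_word_inventory <- function() .function_words

#' @rdname function_word_inventory
#' @export
theme_lexicons <- function() .theme_lexicons

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the published cohort structure: 284 participants of whom
#' 45.1\% carry an MDD diagnosis, per-participant diary counts from a rounded
#' log-normal with median 2 and mean about 11 (floor 1), latent severity
#' following an AR(1) around group means 12.1 (MDD) and 3.5 (HC) with
#' group-specific spread 9.36 / 4.29 on the BDI scale, and six transcript
#' themes of which the first (distress/care) becomes more likely as severity
#' rises. Severity signal is planted at three linguistic levels with
#' decreasing strength: content-word choice (theme prevalence), word order
#' (function-before-content ordering odds), and inflection (suffix odds) —
#' so linguistic perturbations have well-defined targets. The default
#' content-channel strength is scaled so the planted text-embedding signal
#' stays the strongest modality, mirroring the modality ordering such
#' studies report.
#'
#' @param n_participants number of participants.
#' @param mdd_fraction fraction of participants in the MDD group.
#' @param adherence_log_mean,adherence_log_sd log-scale mean and SD of the
#'   per-participant diary-count law (rounded log-normal, floor 1).
#' @param ar_coefficient AR(1) coefficient of the latent severity series,
#'   in [0, 1).
#' @param severity_mean_mdd,severity_mean_hc group means of latent severity
#'   on the BDI scale.
#' @param severity_sd stationary SD of latent severity; length 1 (shared) or
#'   length 2 as c(hc, mdd).
#' @param bdi_noise_sd SD of Gaussian measurement noise added to the latent
#'   severity before rounding/clipping to the 0-63 BDI sum.
#' @param text_signal_r2,audio_signal_r2 target fraction of BDI variance
#'   encoded by the text-like / audio-like embedding provider, in [0, 1).
#' @param embedding_dim embedding dimensionality per modality.
#' @param n_themes number of transcript themes (up to 6).
#' @param theme_severity_slopes per-theme log-odds slope of theme probability
#'   on standardised severity.
#' @param order_slope log-odds slope of canonical (function-before-content)
#'   word order on standardised severity.
#' @param suffix_slope log-odds slope of the marked inflection suffix on
#'   standardised severity.
#' @param tokens_per_diary expected transcript length in tokens.
#' @param bdi_prob probability that a diary has a BDI self-report within the
#'   pairing window.
#' @param seed integer seed; all cohort randomness derives from it through
#'   named sub-streams.
#' @return a `voicebdi_cohort_config` list.
#' @export
cohort_config <- function(n_participants = 284,
                          mdd_fraction = 0.451,
                          adherence_log_mean = log(2),
                          adherence_log_sd = 1.85,
                          ar_coefficient = 0.7,
                          severity_mean_mdd = 12.1,
                          severity_mean_hc = 3.5,
                          severity_sd = c(4.29, 9.36),
                          bdi_noise_sd = 1.5,
                          text_signal_r2 = 0.35,
                          audio_signal_r2 = 0.05,
                          embedding_dim = 256,
                          n_themes = 6,
                          theme_severity_slopes = 0.7 * c(1.0, -0.2, -0.3,
                                                          -0.6, -0.8, -0.8),
                          order_slope = 0.6,
                          suffix_slope = 0.3,
                          tokens_per_diary = 60,
                          bdi_prob = 0.97,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    mdd_fraction = mdd_fraction,
    adherence_log_mean = adherence_log_mean,
    adherence_log_sd = adherence_log_sd,
    ar_coefficient = ar_coefficient,
    severity_mean_mdd = severity_mean_mdd,
    severity_mean_hc = severity_mean_hc,
    severity_sd = if (length(severity_sd) == 1L) rep(severity_sd, 2L)
                  else severity_sd,
    bdi_noise_sd = bdi_noise_sd,
    text_signal_r2 = text_signal_r2,
    audio_signal_r2 = audio_signal_r2,
    embedding_dim = as.integer(embedding_dim),
    n_themes = as.integer(n_themes),
    theme_severity_slopes = theme_severity_slopes[seq_len(n_themes)],
    order_slope = order_slope,
    suffix_slope = suffix_slope,
    tokens_per_diary = tokens_per_diary,
    bdi_prob = bdi_prob,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "voicebdi_cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid cohort config: ", msg,
                                         call. = FALSE)
  chk(cfg$n_participants >= 1, "n_participants must be >= 1")
  chk(cfg$mdd_fraction >= 0 && cfg$mdd_fraction <= 1,
      "mdd_fraction must lie in [0, 1]")
  chk(cfg$ar_coefficient >= 0 && cfg$ar_coefficient < 1,
      "ar_coefficient must lie in [0, 1)")
  chk(cfg$adherence_log_sd >= 0, "adherence_log_sd must be >= 0")
  chk(all(cfg$severity_sd > 0), "severity_sd must be positive")
  chk(cfg$text_signal_r2 >= 0 && cfg$text_signal_r2 < 1,
      "text_signal_r2 must lie in [0, 1)")
  chk(cfg$audio_signal_r2 >= 0 && cfg$audio_signal_r2 < 1,
      "audio_signal_r2 must lie in [0, 1)")
  chk(cfg$n_themes >= 1 && cfg$n_themes <= length(.theme_lexicons),
      "n_themes out of range")
  chk(length(cfg$theme_severity_slopes) == cfg$n_themes,
      "theme_severity_slopes length must equal n_themes")
  chk(cfg$bdi_prob >= 0 && cfg$bdi_prob <= 1, "bdi_prob must lie in [0, 1]")
  invisible(cfg)
}

# Fixed BDI item loadings: mild variation across the 21 items, summing to 1.
.bdi_item_loadings <- {
  w <- 1 + 0.5 * sin(seq(0, 2 * pi, length.out = 21))
  w / sum(w)
}

#' Convert a latent severity value into a 21-item BDI record
#'
#' The sum is `clip(round(latent + noise), 0, 63)`; the 21 item scores (each
#' 0-3) are allocated to match the sum exactly by proportional loading with
#' largest-remainder rounding, so `sum(items) == sum` by construction.
#'
#' @param latent latent severity on the BDI scale.
#' @param noise_sd SD of Gaussian noise added before rounding; draws come
#'   from the current RNG state.
#' @return list with `sum` (integer in 0..63) and `items` (21 integers 0..3).
#' @export
severity_to_bdi <- function(latent, noise_sd = 1.5) {
  s <- round(latent + stats::rnorm(1L, 0, noise_sd))
  s <- as.integer(min(max(s, 0), 63))
  list(sum = s, items = allocate_bdi_items(s))
}

# Largest-remainder allocation of `total` points over 21 items capped at 3.
allocate_bdi_items <- function(total) {
  stopifnot(total >= 0, total <= 63)
  target <- .bdi_item_loadings * total
  items <- pmin(floor(target), 3)
  left <- total - sum(items)
  # distribute the remainder by largest fractional part among uncapped items
  frac <- target - floor(target)
  ord <- order(frac, seq_along(frac), decreasing = TRUE)
  i <- 1L
  while (left > 0) {
    j <- ord[i]
    if (items[j] < 3) {
      items[j] <- items[j] + 1
      left <- left - 1
    }
    i <- if (i == 21L) 1L else i + 1L
  }
  as.integer(items)
}

#' Generate one role-tagged transcript
#'
#' Sentences are assembled from theme-specific content lexicons interleaved
#' with a fixed function-word inventory. Each token carries a role tag
#' (function, content, numeral, proper_noun) and a (surface, lemma) pair;
#' inflected surfaces are produced by suffixing rules. Three severity-linked
#' channels are planted: theme choice follows the mixture (itself
#' severity-linked upstream), the odds of canonical function-before-content
#' order rise with `order_slope`, and the odds of the marked suffix rise with
#' `suffix_slope`.
#'
#' @param theme_mixture probability vector over themes (sums to 1).
#' @param severity latent severity on the BDI scale.
#' @param length target number of non-punctuation tokens (pairs are emitted,
#'   so the realised count is `2 * floor(length / 2)` plus rare extras).
#' @param order_slope,suffix_slope log-odds slopes on standardised severity.
#' @return data.frame with columns surface, lemma, role, sentence.
#' @export
generate_transcript <- function(theme_mixture, severity, length = 60,
                                order_slope = 0.6, suffix_slope = 0.3) {
  stopifnot(abs(sum(theme_mixture) - 1) < 1e-9, all(theme_mixture >= -1e-12))
  if (length <= 0) {
    return(data.frame(surface = character(), lemma = character(),
                      role = character(), sentence = integer(),
                      stringsAsFactors = FALSE))
  }
  z <- (severity - 8) / 8 # standardised severity
  n_pairs <- max(1L, floor(length / 2))
  themes <- sample.int(length(theme_mixture), n_pairs, replace = TRUE,
                       prob = theme_mixture)
  lex <- .theme_lexicons[seq_along(theme_mixture)]
  content_lemma <- vapply(themes, function(k) sample(lex[[k]], 1L),
                          character(1))
  # inflection channel: the marked suffix "te" carries the severity link;
  # a rare neutral "en" suffix adds inflection variety without signal
  p_marked <- stats::plogis(stats::qlogis(0.25) + suffix_slope * z)
  marked <- stats::runif(n_pairs) < p_marked
  weak <- stats::runif(n_pairs) < 0.15
  suffix <- ifelse(marked, "te", ifelse(weak, "en", ""))
  content_surface <- paste0(content_lemma, suffix)
  func <- sample(.function_words, n_pairs, replace = TRUE)
  surface <- as.vector(rbind(func, content_surface))
  lemma <- as.vector(rbind(func, content_lemma))
  role <- as.vector(rbind(rep("function", n_pairs),
                          rep("content", n_pairs)))
  # word-order channel: every sentence opens with the marker bigram
  # "ich habe" (canonical) or its inversion "habe ich"; the inversion odds
  # fall with severity, so sentence-internal order carries signal through a
  # small, learnable bigram vocabulary
  n_sent <- max(1L, ceiling(n_pairs / 4))
  canonical <- stats::runif(n_sent) < stats::plogis(order_slope * z)
  marker <- lapply(canonical, function(cn) {
    if (cn) c("ich", "habe") else c("habe", "ich")
  })
  sent_of_pair <- rep(seq_len(n_sent), each = 4, length.out = n_pairs)
  surf_s <- split(surface, rep(sent_of_pair, each = 2))
  lem_s <- split(lemma, rep(sent_of_pair, each = 2))
  role_s <- split(role, rep(sent_of_pair, each = 2))
  surface <- unlist(lapply(seq_len(n_sent), function(s) {
    c(marker[[s]], surf_s[[s]])
  }), use.names = FALSE)
  lemma <- unlist(lapply(seq_len(n_sent), function(s) {
    c(marker[[s]], lem_s[[s]])
  }), use.names = FALSE)
  role <- unlist(lapply(seq_len(n_sent), function(s) {
    c("function", "function", role_s[[s]])
  }), use.names = FALSE)
  sent_len <- vapply(seq_len(n_sent), function(s) {
    length(surf_s[[s]]) + 2L
  }, integer(1))
  # occasional numerals and proper nouns
  n_tok <- length(surface)
  extra <- stats::runif(n_tok)
  is_num <- extra < 0.02
  is_prop <- extra >= 0.02 & extra < 0.04
  if (any(is_num)) {
    v <- sample(.numerals, sum(is_num), replace = TRUE)
    surface[is_num] <- v
    lemma[is_num] <- v
    role[is_num] <- "numeral"
  }
  if (any(is_prop)) {
    v <- sample(.proper_nouns, sum(is_prop), replace = TRUE)
    surface[is_prop] <- v
    lemma[is_prop] <- v
    role[is_prop] <- "proper_noun"
  }
  sentence <- rep(seq_len(n_sent), sent_len)
  data.frame(surface = surface, lemma = lemma, role = role,
             sentence = as.integer(sentence), stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `config$seed`; every stage (participants, adherence,
#' trajectories, timestamps, text, BDI noise) draws from its own named
#' sub-stream, so changing one knob does not reshuffle unrelated draws.
#'
#' @param config a [cohort_config()].
#' @return a `voicebdi_cohort` list with elements `participants`, `diaries`,
#'   `tokens`, `bdi`, `trajectories`, `theme_mixtures`, `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_participants
  n_mdd <- round(n * cfg$mdd_fraction)
  group <- c(rep("MDD", n_mdd), rep("HC", n - n_mdd))
  pid <- sprintf("P%03d", seq_len(n))

  participants <- with_seed(substream_seed(cfg$seed, "participants"), {
    age <- ifelse(group == "MDD", stats::rnorm(n, 49.7, 11.5),
                  stats::rnorm(n, 53.0, 11.7))
    sex_p <- ifelse(group == "MDD", 0.727, 0.686)
    sex <- ifelse(stats::runif(n) < sex_p, "female", "male")
    data.frame(participant_id = pid, group = group,
               age = round(pmax(18, age), 1), sex = sex,
               stringsAsFactors = FALSE)
  })

  counts <- with_seed(substream_seed(cfg$seed, "adherence"), {
    if (cfg$adherence_log_sd == 0) {
      rep(max(1L, as.integer(round(exp(cfg$adherence_log_mean)))), n)
    } else {
      pmax(1L, as.integer(round(stats::rlnorm(n, cfg$adherence_log_mean,
                                              cfg$adherence_log_sd))))
    }
  })

  mu <- ifelse(group == "MDD", cfg$severity_mean_mdd, cfg$severity_mean_hc)
  sd_g <- ifelse(group == "MDD", cfg$severity_sd[2], cfg$severity_sd[1])
  phi <- cfg$ar_coefficient
  trajectories <- with_seed(substream_seed(cfg$seed, "trajectory"), {
    lapply(seq_len(n), function(i) {
      m <- counts[i]
      s <- numeric(m)
      s[1] <- stats::rnorm(1, mu[i], sd_g[i])
      if (m > 1) {
        innov_sd <- sd_g[i] * sqrt(1 - phi^2)
        for (t in 2:m) {
          s[t] <- mu[i] + phi * (s[t - 1] - mu[i]) +
            stats::rnorm(1, 0, innov_sd)
        }
      }
      s
    })
  })
  names(trajectories) <- pid

  start_day <- with_seed(substream_seed(cfg$seed, "timestamps"), {
    sample.int(1200L, n, replace = TRUE)
  })
  diary_days <- with_seed(substream_seed(cfg$seed, "timestamps/jitter"), {
    lapply(seq_len(n), function(i) {
      start_day[i] + 7 * (seq_len(counts[i]) - 1) +
        round(stats::runif(counts[i], -1, 1))
    })
  })

  n_diaries <- sum(counts)
  diary_pid <- rep(pid, counts)
  diary_id <- sprintf("D%05d", seq_len(n_diaries))
  severity <- unlist(trajectories, use.names = FALSE)
  day <- unlist(diary_days, use.names = FALSE)

  # theme mixtures: softmax of base log-weights plus severity-linked slopes,
  # sharpened toward a sampled dominant theme so clusters are recoverable
  slopes <- cfg$theme_severity_slopes
  mixtures <- with_seed(substream_seed(cfg$seed, "themes"), {
    z <- (severity - 8) / 8
    logits <- outer(z, slopes)
    p <- exp(logits - apply(logits, 1, max))
    p <- p / rowSums(p)
    dom <- vapply(seq_len(n_diaries),
                  function(i) sample.int(cfg$n_themes, 1L, prob = p[i, ]),
                  integer(1))
    m <- 0.25 * p
    m[cbind(seq_len(n_diaries), dom)] <-
      m[cbind(seq_len(n_diaries), dom)] + 0.75
    m / rowSums(m)
  })
  rownames(mixtures) <- diary_id
  colnames(mixtures) <- names(.theme_lexicons)[seq_len(cfg$n_themes)]

  tokens <- with_seed(substream_seed(cfg$seed, "text"), {
    tl <- lapply(seq_len(n_diaries), function(i) {
      tr <- generate_transcript(mixtures[i, ], severity[i],
                                length = cfg$tokens_per_diary,
                                order_slope = cfg$order_slope,
                                suffix_slope = cfg$suffix_slope)
      if (nrow(tr)) tr$diary_id <- diary_id[i]
      tr
    })
    do.call(rbind, tl)
  })

  durations <- with_seed(substream_seed(cfg$seed, "duration"), {
    dur <- stats::runif(n_diaries, 60, 180)
    pause_frac <- stats::plogis(stats::rnorm(n_diaries, -1.5, 0.4) +
                                  0.03 * (severity - 8))
    data.frame(duration_s = round(dur, 1),
               pause_s = round(dur * pause_frac, 1))
  })

  bdi <- with_seed(substream_seed(cfg$seed, "noise"), {
    has_bdi <- stats::runif(n_diaries) < cfg$bdi_prob
    idx <- which(has_bdi)
    offs <- round(stats::runif(length(idx), -3, 3))
    recs <- lapply(seq_along(idx), function(j) {
      r <- severity_to_bdi(severity[idx[j]], cfg$bdi_noise_sd)
      c(r$sum, r$items)
    })
    m <- do.call(rbind, recs)
    out <- data.frame(bdi_id = sprintf("B%05d", seq_along(idx)),
                      participant_id = diary_pid[idx],
                      day = day[idx] + offs,
                      stringsAsFactors = FALSE)
    items <- as.data.frame(m[, -1, drop = FALSE])
    names(items) <- paste0("item_", 1:21)
    out <- cbind(out, items)
    out$sum <- as.integer(m[, 1])
    out
  })
  origin <- as.Date("2019-05-01")
  bdi$timestamp <- origin + bdi$day
  bdi$day <- NULL

  diaries <- data.frame(diary_id = diary_id,
                        participant_id = diary_pid,
                        timestamp = origin + day,
                        duration_s = durations$duration_s,
                        pause_s = durations$pause_s,
                        severity = severity,
                        paired_bdi_id = NA_character_,
                        stringsAsFactors = FALSE)

  structure(list(participants = participants,
                 diaries = diaries,
                 tokens = tokens,
                 bdi = bdi,
                 trajectories = trajectories,
                 theme_mixtures = mixtures,
                 config = cfg),
            class = "voicebdi_cohort")
}

#' @export
print.voicebdi_cohort <- function(x, ...) {
  cat("voicebdi synthetic cohort:",
      nrow(x$participants), "participants,",
      nrow(x$diaries), "diaries,",
      nrow(x$bdi), "BDI records\n")
  print(table(x$participants$group))
  invisible(x)
}

#' Extract one diary's token table
#'
#' @param cohort a `voicebdi_cohort`.
#' @param diary_id the diary identifier.
#' @return data.frame of role-tagged tokens in order.
#' @export
diary_tokens <- function(cohort, diary_id) {
  tk <- cohort$tokens
  tk[tk$diary_id == diary_id, c("surface", "lemma", "role", "sentence")]
}
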