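#' @name text_features
#' @title Normalised text, timing/lexical statistics, silence detection,
#'   TF-IDF
NULL

# Fixed extra stop words beyond the generator's function-word inventory.
.extra_stopwords <- c("am", "im", "an", "um", "als", "wie", "oder", "noch",
                      "schon", "nur", "man", "wir", "sie", "er")

#' Normalise a diary transcript
#'
#' Lowercases surfaces, substitutes lemmas, and drops stop words (the
#' function-word inventory plus a fixed list) and punctuation-only tokens.
#' An empty result is allowed.
#'
#' @param tokens data.frame with surface, lemma, role columns (one diary).
#' @return character vector of normalised lemmas.
#' @export
normalize_text <- function(tokens) {
  if (nrow(tokens) == 0) return(character())
  lem <- tolower(ifelse(is.na(tokens$lemma) | tokens$lemma == "",
                        tokens$surface, tokens$lemma))
  stopw <- c(.function_words, .extra_stopwords)
  keep <- !(lem %in% stopw) &
    !(tolower(tokens$surface) %in% stopw) &
    !(tokens$role %in% c("function", "punct")) &
    grepl("[[:alnum:]]", lem)
  lem <- gsub("[[:punct:]]", "", lem[keep])
  lem[nzchar(lem)]
}

#' Silence-detection specification
#'
#' @param threshold_db RMS level threshold in dB relative to full scale.
#' @param min_silence_s minimum silence duration in seconds.
#' @return a list spec.
#' @export
silence_spec <- function(threshold_db = -30, min_silence_s = 0.5) {
  stopifnot(threshold_db < 0, min_silence_s > 0)
  list(threshold_db = threshold_db, min_silence_s = min_silence_s)
}

#' Detect silences in an amplitude signal
#'
#' Windowed RMS (50 ms windows, 50\% overlap) in dB relative to full scale;
#' contiguous runs below the threshold lasting at least `min_silence_s`
#' are reported as silences.
#'
#' @param samples numeric amplitude vector in [-1, 1].
#' @param rate sampling rate in Hz.
#' @param spec a [silence_spec()].
#' @return data.frame with start_s, end_s (sorted, non-overlapping).
#' @export
detect_silences <- function(samples, rate, spec = silence_spec()) {
  stopifnot(rate > 0)
  empty <- data.frame(start_s = numeric(), end_s = numeric())
  n <- length(samples)
  if (n == 0) return(empty)
  win <- max(1L, round(0.050 * rate))
  hop <- max(1L, round(0.025 * rate))
  starts <- seq(1L, n, by = hop)
  rms_db <- vapply(starts, function(s) {
    seg <- samples[s:min(s + win - 1L, n)]
    r <- sqrt(mean(seg^2))
    if (r <= 0) -Inf else 20 * log10(r)
  }, numeric(1))
  below <- rms_db < spec$threshold_db
  if (!any(below)) return(empty)
  r <- rle(below)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  out <- empty
  total <- n / rate
  for (k in which(r$values)) {
    t0 <- (starts[starts_idx[k]] - 1L) / rate
    t1 <- min((starts[ends_idx[k]] - 1L + win) / rate, total)
    if (t1 - t0 >= spec$min_silence_s) {
      out <- rbind(out, data.frame(start_s = t0, end_s = t1))
    }
  }
  out[order(out$start_s), , drop = FALSE]
}

.timing_lexical_names <- c(
  "speech_time_s", "pause_time_s", "pause_count", "pause_speech_ratio",
  "articulation_rate", "token_count", "type_count", "type_token_ratio",
  "mean_word_length", "sentence_count", "mean_sentence_length",
  "function_word_share", "content_word_share", "numeral_count",
  "proper_noun_count", "filler_share", "negation_share",
  "first_person_share")

#' The 18 timing and lexical statistics for one diary
#'
#' Pause time is the summed silence duration (or a generator-provided pause
#' total treated as one pause); speech time is duration minus pause time;
#' rates are per second of speech time. Invariant to sentence order.
#'
#' @param tokens data.frame with surface, lemma, role, sentence (one diary).
#' @param duration_s total recording duration in seconds.
#' @param silences data.frame from [detect_silences()], or NULL.
#' @param pause_s total pause seconds when no silence list is available.
#' @return named numeric vector of length 18, with attribute
#'   `zero_duration` flagging rate statistics forced to 0.
#' @export
timing_lexical <- function(tokens, duration_s, silences = NULL,
                           pause_s = NULL) {
  if (!is.null(silences) && nrow(silences)) {
    pause_time <- sum(silences$end_s - silences$start_s)
    pause_count <- nrow(silences)
  } else if (!is.null(pause_s)) {
    pause_time <- pause_s
    pause_count <- as.numeric(pause_s > 0)
  } else {
    pause_time <- 0
    pause_count <- 0
  }
  pause_time <- min(pause_time, duration_s)
  speech_time <- duration_s - pause_time
  zero_flag <- speech_time <= 0
  surf <- tolower(tokens$surface)
  n_tok <- length(surf)
  n_type <- length(unique(surf))
  share <- function(x) if (n_tok == 0) 0 else mean(x)
  sent <- if (n_tok) length(unique(tokens$sentence)) else 0
  v <- c(
    speech_time_s = speech_time,
    pause_time_s = pause_time,
    pause_count = pause_count,
    pause_speech_ratio = if (speech_time > 0) pause_time / speech_time else 0,
    articulation_rate = if (speech_time > 0) n_tok / speech_time else 0,
    token_count = n_tok,
    type_count = n_type,
    type_token_ratio = if (n_tok > 0) n_type / n_tok else 0,
    mean_word_length = if (n_tok > 0) mean(nchar(surf)) else 0,
    sentence_count = sent,
    mean_sentence_length = if (sent > 0) n_tok / sent else 0,
    function_word_share = share(tokens$role == "function"),
    content_word_share = share(tokens$role == "content"),
    numeral_count = sum(tokens$role == "numeral"),
    proper_noun_count = sum(tokens$role == "proper_noun"),
    filler_share = share(surf %in% .filler_words),
    negation_share = share(surf %in% .negation_words),
    first_person_share = share(surf %in% .first_person_words)
  )
  names(v) <- .timing_lexical_names
  attr(v, "zero_duration") <- zero_flag
  v
}

#' Timing/lexical feature matrix for a cohort
#'
#' @param cohort a `voicebdi_cohort` (uses generator pause totals).
#' @param diary_ids diaries to include (default all, in order).
#' @return numeric matrix, one row per diary, 18 named columns.
#' @export
timing_lexical_matrix <- function(cohort, diary_ids = cohort$diaries$diary_id) {
  tok_split <- split(cohort$tokens, cohort$tokens$diary_id)
  dd <- cohort$diaries[match(diary_ids, cohort$diaries$diary_id), ]
  m <- t(vapply(seq_along(diary_ids), function(i) {
    tk <- tok_split[[diary_ids[i]]]
    if (is.null(tk)) {
      tk <- data.frame(surface = character(), lemma = character(),
                       role = character(), sentence = integer())
    }
    as.numeric(timing_lexical(tk, dd$duration_s[i], pause_s = dd$pause_s[i]))
  }, numeric(18)))
  colnames(m) <- .timing_lexical_names
  rownames(m) <- diary_ids
  m
}

# ---- TF-IDF ---------------------------------------------------------------

ngrams_of <- function(tokens, ngram_range) {
  out <- character()
  if (ngram_range[1] <= 1 && ngram_range[2] >= 1) out <- c(out, tokens)
  if (ngram_range[2] >= 2 && length(tokens) >= 2) {
    out <- c(out, paste(tokens[-length(tokens)], tokens[-1]))
  }
  out
}

#' Fit a TF-IDF model on a normalised-text corpus
#'
#' Smoothed idf `ln((1+N)/(1+df)) + 1` with L2-normalised rows; 1-2-gram
#' features by default. Fit only on training partitions; unseen n-grams are
#' ignored at transform time.
#'
#' @param corpus list of character vectors (normalised tokens per document).
#' @param ngram_range integer pair, inclusive n-gram range.
#' @param min_df minimum document frequency for a term to enter the
#'   vocabulary.
#' @param max_features cap on vocabulary size (most frequent kept).
#' @return a `voicebdi_tfidf` model (vocabulary + idf weights).
#' @export
tfidf_fit <- function(corpus, ngram_range = c(1, 2), min_df = 1,
                      max_features = 4000) {
  if (length(corpus) == 0) stop("empty training corpus", call. = FALSE)
  grams <- lapply(corpus, ngrams_of, ngram_range = ngram_range)
  df_tab <- table(unlist(lapply(grams, unique)))
  df_tab <- df_tab[df_tab >= min_df]
  if (length(df_tab) == 0) stop("empty vocabulary after min_df",
                                call. = FALSE)
  if (length(df_tab) > max_features) {
    tot <- table(unlist(grams))
    keep <- names(sort(tot[names(df_tab)], decreasing = TRUE))[
      seq_len(max_features)]
    df_tab <- df_tab[keep]
  }
  vocab <- sort(names(df_tab))
  dfv <- as.numeric(df_tab[vocab])
  n_docs <- length(corpus)
  idf <- log((1 + n_docs) / (1 + dfv)) + 1
  structure(list(vocabulary = vocab, idf = idf, n_docs = n_docs,
                 ngram_range = ngram_range),
            class = "voicebdi_tfidf")
}

#' Transform documents with a fitted TF-IDF model
#'
#' @param model a `voicebdi_tfidf`.
#' @param corpus list of character vectors.
#' @return dense numeric matrix (documents x vocabulary), L2 rows (zero rows
#'   for empty documents).
#' @export
tfidf_transform <- function(model, corpus) {
  v <- model$vocabulary
  m <- matrix(0, nrow = length(corpus), ncol = length(v),
              dimnames = list(NULL, v))
  for (i in seq_along(corpus)) {
    g <- ngrams_of(corpus[[i]], model$ngram_range)
    g <- g[g %in% v]
    if (length(g)) {
      tf <- table(g)
      m[i, names(tf)] <- as.numeric(tf)
    }
  }
  m <- sweep(m, 2, model$idf, `*`)
  l2_normalize_rows(m)
}

#' Serialise / load a TF-IDF model as JSON
#'
#' @param model a `voicebdi_tfidf`.
#' @param path JSON file path.
#' @return the path / the model.
#' @export
tfidf_save <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tfidf_save
#' @export
tfidf_load <- function(path) {
  m <- jsonlite::fromJSON(path)
  structure(list(vocabulary = m$vocabulary, idf = m$idf, n_docs = m$n_docs,
                 ngram_range = m$ngram_range),
            class = "voicebdi_tfidf")
}

#' Normalised corpus for a set of diaries
#'
#' @param cohort a `voicebdi_cohort`.
#' @param diary_ids diaries to include, in order.
#' @return named list of character vectors.
#' @export
normalized_corpus <- function(cohort, diary_ids = cohort$diaries$diary_id) {
  tok_split <- split(cohort$tokens, cohort$tokens$diary_id)
  out <- lapply(diary_ids, function(id) {
    tk <- tok_split[[id]]
    if (is.null(tk)) character() else normalize_text(tk)
  })
  names(out) <- diary_ids
  out
}

#' TF-IDF modality matrix for a cohort
#'
#' Convenience wrapper: fits on the given diaries and transforms them. For
#' leakage-safe modelling the benchmark refits TF-IDF inside training
#' partitions; this full-corpus variant exists for descriptive analyses and
#' as a fixed feature matrix whose columns are recomputed per fold by the
#' benchmark when `refit_per_fold` is requested there.
#'
#' @param cohort a `voicebdi_cohort`.
#' @param diary_ids diaries to include.
#' @param ... passed to [tfidf_fit()].
#' @return list(matrix, model).
#' @export
tfidf_matrix <- function(cohort, diary_ids = cohort$diaries$diary_id, ...) {
  corp <- normalized_corpus(cohort, diary_ids)
  model <- tfidf_fit(corp, ...)
  m <- tfidf_transform(model, corp)
  rownames(m) <- diary_ids
  list(matrix = m, model = model)
}
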