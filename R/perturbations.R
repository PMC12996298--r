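#' @name perturbations
#' @title Controlled linguistic transforms of verbatim transcripts
#'
#' @description
#' Six transforms applied to role-tagged token tables before embedding:
#' within-sentence word-order shuffling, lemmatisation (numerals and proper
#' nouns kept), vowel masking, intra-word interior shuffling (length >= 5),
#' the function-word skeleton, and the content-only complement. All are pure
#' functions of (tokens, seed). Punctuation tokens (role "punct"), when
#' present, stay glued to the token that precedes them.
NULL

# Apply a per-diary transform to a cohort-level token table.
apply_by_diary <- function(tokens, f) {
  parts <- split(tokens, tokens$diary_id)
  out <- do.call(rbind, lapply(parts, f))
  rownames(out) <- NULL
  out
}

# Units for order shuffling: each punct token is glued to its predecessor.
shuffle_sentence <- function(tk) {
  n <- nrow(tk)
  if (n <= 1) return(tk)
  unit <- cumsum(tk$role != "punct")
  unit[unit == 0] <- 1 # leading punctuation stays first
  groups <- split(seq_len(n), unit)
  perm <- sample(length(groups))
  tk[unlist(groups[perm]), , drop = FALSE]
}

#' Word-order disruption
#'
#' One uniformly random permutation per sentence; the token multiset per
#' sentence and the sentence boundaries are preserved.
#'
#' @param tokens cohort- or diary-level token table (surface, lemma, role,
#'   sentence, optionally diary_id).
#' @param seed integer seed.
#' @return token table of the same shape.
#' @export
perturb_word_order <- function(tokens, seed) {
  with_seed(substream_seed(seed, "word_order"), {
    f <- function(tk) {
      sent <- split(seq_len(nrow(tk)), tk$sentence)
      parts <- lapply(sent, function(ix) shuffle_sentence(tk[ix, , drop = FALSE]))
      out <- do.call(rbind, parts)
      rownames(out) <- NULL
      out
    }
    if ("diary_id" %in% names(tokens)) apply_by_diary(tokens, f) else f(tokens)
  })
}

#' Inflection neutralisation (lemmatisation)
#'
#' Replaces each surface with its lemma; numerals and proper nouns are left
#' unchanged. Order is unchanged; a missing lemma keeps the surface with a
#' warning.
#'
#' @param tokens token table.
#' @return token table.
#' @export
perturb_lemmatize <- function(tokens) {
  out <- tokens
  missing <- is.na(out$lemma) | out$lemma == ""
  if (any(missing)) {
    warning(sum(missing), " tokens without lemma kept as surface")
  }
  repl <- !(out$role %in% c("numeral", "proper_noun", "punct")) & !missing
  out$surface[repl] <- out$lemma[repl]
  out
}

#' Vowel masking
#'
#' Case-insensitive replacement of the German vowels a, e, i, o, u, ä, ö, ü
#' by "_"; string length is preserved per token.
#'
#' @param tokens token table.
#' @return token table.
#' @export
perturb_vowel_mask <- function(tokens) {
  out <- tokens
  out$surface <- chartr("aeiouäöüAEIOUÄÖÜ",
                        strrep("_", 16), out$surface)
  out
}

#' Intra-word interior shuffling
#'
#' Tokens shorter than 5 characters are unchanged; longer tokens keep their
#' first and last character while the interior is uniformly permuted.
#'
#' @param tokens token table.
#' @param seed integer seed.
#' @return token table.
#' @export
perturb_intraword_shuffle <- function(tokens, seed) {
  with_seed(substream_seed(seed, "intraword"), {
    out <- tokens
    long <- nchar(out$surface) >= 5
    out$surface[long] <- vapply(out$surface[long], function(s) {
      ch <- strsplit(s, "")[[1]]
      n <- length(ch)
      paste0(ch[1], paste(ch[sample(2:(n - 1)) ], collapse = ""), ch[n])
    }, character(1), USE.NAMES = FALSE)
    out
  })
}

#' Function-word skeleton / content-only variant
#'
#' The skeleton keeps tokens with role "function" (punctuation included);
#' the content-only variant keeps the complement (content, numerals, proper
#' nouns). Together they partition the diary; order is preserved.
#'
#' @param tokens token table.
#' @return token table.
#' @export
perturb_function_skeleton <- function(tokens) {
  tokens[tokens$role %in% c("function", "punct"), , drop = FALSE]
}

#' @rdname perturb_function_skeleton
#' @export
perturb_content_only <- function(tokens) {
  tokens[!(tokens$role %in% c("function", "punct")), , drop = FALSE]
}

#' Apply a named perturbation to a cohort
#'
#' @param cohort a `voicebdi_cohort`.
#' @param kind one of identity, word_order, lemmatize, vowel_mask,
#'   intraword_shuffle, function_skeleton, content_only.
#' @param seed seed (required for the stochastic kinds).
#' @return the cohort with its token table transformed.
#' @export
perturb_cohort <- function(cohort,
                           kind = c("identity", "word_order", "lemmatize",
                                    "vowel_mask", "intraword_shuffle",
                                    "function_skeleton", "content_only"),
                           seed = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("word_order", "intraword_shuffle") && is.null(seed)) {
    stop("seed required for stochastic perturbation '", kind, "'",
         call. = FALSE)
  }
  tk <- cohort$tokens
  cohort$tokens <- switch(
    kind,
    identity = tk,
    word_order = perturb_word_order(tk, seed),
    lemmatize = perturb_lemmatize(tk),
    vowel_mask = perturb_vowel_mask(tk),
    intraword_shuffle = perturb_intraword_shuffle(tk, seed),
    function_skeleton = apply_by_diary(tk, perturb_function_skeleton),
    content_only = apply_by_diary(tk, perturb_content_only))
  cohort
}

#' Run the perturbation study
#'
#' Re-embeds the cohort under each condition and re-runs the identical
#' z-score/PCA/SVR pipeline on the identical participant-grouped fold plan,
#' then compares each condition with the unperturbed baseline by paired
#' sign-flip permutation tests on fold-wise metrics, with Cohen's d_z.
#'
#' @param cohort a `voicebdi_cohort`.
#' @param provider the text embedding provider.
#' @param kinds perturbation kinds to run (baseline "identity" is always
#'   included first).
#' @param plan a [build_fold_plan()]; built from the cohort if NULL.
#' @param space a [search_space()].
#' @param seed seed for the stochastic perturbations.
#' @param n_perm sign-flip permutation iterations.
#' @return list with `results` (tidy data.frame: condition, fold, mae, r2)
#'   and `comparisons` (per condition vs baseline: delta_mae, delta_r2,
#'   p-values, effect sizes).
#' @export
run_perturbation_study <- function(cohort, provider,
                                   kinds = c("word_order", "lemmatize",
                                             "vowel_mask",
                                             "intraword_shuffle",
                                             "function_skeleton",
                                             "content_only"),
                                   plan = NULL, space = search_space(),
                                   seed = 1L, n_perm = 1000) {
  mt <- modeling_table(cohort)
  if (is.null(plan)) {
    plan <- build_fold_plan(unique(mt$participant_id), seed = seed)
  }
  conditions <- c("identity", kinds)
  fits <- list()
  for (kind in conditions) {
    pc <- perturb_cohort(cohort, kind, seed = seed)
    mm <- build_modality_matrix(pc, provider, mt$diary_id)
    fits[[kind]] <- fit_eval_single(mm, mt$bdi_sum, mt$participant_id,
                                    plan, space, model_name = kind)
  }
  results <- do.call(rbind, lapply(conditions, function(k) {
    data.frame(condition = k, fold = seq_along(fits[[k]]$fold_mae),
               mae = fits[[k]]$fold_mae, r2 = fits[[k]]$fold_r2,
               stringsAsFactors = FALSE)
  }))
  base <- fits[["identity"]]
  comparisons <- do.call(rbind, lapply(kinds, function(k) {
    dm <- fits[[k]]$fold_mae - base$fold_mae
    dr <- fits[[k]]$fold_r2 - base$fold_r2
    tm <- signflip_test(paired_fold_diffs(k, "identity", "mae", dm,
                                          plan$plan_hash, plan$plan_hash),
                        n_perm = n_perm, seed = substream_seed(seed, k))
    tr <- signflip_test(paired_fold_diffs(k, "identity", "r2", dr,
                                          plan$plan_hash, plan$plan_hash),
                        n_perm = n_perm,
                        seed = substream_seed(seed, paste0(k, "/r2")))
    data.frame(condition = k,
               delta_mae = mean(dm), p_mae = tm$p, dz_mae = cohen_dz(dm)$dz,
               delta_r2 = mean(dr), p_r2 = tr$p,
               stringsAsFactors = FALSE)
  }))
  list(results = results, comparisons = comparisons, fits = fits,
       plan = plan)
}
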