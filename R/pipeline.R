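#' @name pipeline
#' @title Seeded end-to-end runs and report generation
NULL

#' Configuration for an end-to-end run
#'
#' @param cohort a [cohort_config()].
#' @param space a [search_space()].
#' @param n_outer,n_inner fold counts.
#' @param embedding_dim embedding dimensionality.
#' @param perturbation_kinds perturbation conditions to run.
#' @param topic_k consolidated theme count.
#' @param seed global seed; every stage receives a derived sub-stream seed.
#' @return a `voicebdi_run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       space = search_space(budget = 10),
                       n_outer = 5, n_inner = 3,
                       embedding_dim = 128,
                       perturbation_kinds = c("word_order", "lemmatize",
                                              "function_skeleton"),
                       topic_k = 6,
                       seed = 1L) {
  structure(list(cohort = cohort, space = space, n_outer = n_outer,
                 n_inner = n_inner, embedding_dim = embedding_dim,
                 perturbation_kinds = perturbation_kinds,
                 topic_k = topic_k, seed = as.integer(seed)),
            class = "voicebdi_run_config")
}

#' Run the full analysis pipeline and write reports
#'
#' Executes generate -> pair -> features/embeddings -> benchmark (singles,
#' dummy, fusion, classification, subgroups, idiographic) -> model
#' comparisons -> calibration -> perturbation study -> topics, writing a
#' leaderboard, comparison, calibration, perturbation and topic tables plus
#' a manifest with the configuration hash and all stage seeds. Stages write
#' their outputs as they finish, so a failure retains partial results.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisible list of in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  manifest <- list(config_hash = object_hash(unclass(config)),
                   seed = seed, stages = list())
  log_stage <- function(name, stage_seed) {
    manifest$stages[[name]] <<- list(seed = stage_seed,
                                     time = format(Sys.time()))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  cfg <- config$cohort
  cfg$seed <- substream_seed(seed, "cohort")
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  log_stage("cohort", cfg$seed)

  mt <- modeling_table(cohort)
  write_modeling_table(cohort, file.path(out_dir, "modeling_table.csv"))
  plan <- build_fold_plan(unique(mt$participant_id), config$n_outer,
                          config$n_inner,
                          seed = substream_seed(seed, "folds"))
  jsonlite::write_json(list(outer = as.list(plan$outer),
                            plan_hash = plan$plan_hash),
                       file.path(out_dir, "foldplan.json"),
                       auto_unbox = TRUE)
  log_stage("folds", plan$seed)

  text_provider <- embedding_provider("text_embedding",
                                      dim = config$embedding_dim,
                                      seed = substream_seed(seed, "emb_text"),
                                      target_r2 = cfg$text_signal_r2)
  audio_provider <- embedding_provider("audio_embedding",
                                       dim = config$embedding_dim,
                                       seed = substream_seed(seed,
                                                             "emb_audio"),
                                       block_weights = c(0.2, 0.2, 0.2, 0.2),
                                       target_r2 = cfg$audio_signal_r2)
  x_text <- build_modality_matrix(cohort, text_provider, mt$diary_id)
  x_audio <- build_modality_matrix(cohort, audio_provider, mt$diary_id)
  x_timing <- timing_lexical_matrix(cohort, mt$diary_id)
  tfidf_builder <- make_tfidf_builder(cohort)
  log_stage("features", text_provider$seed)

  space <- config$space
  res <- list(
    text_embedding = fit_eval_single(x_text, mt$bdi_sum, mt$participant_id,
                                     plan, space, "text_embedding"),
    tfidf = fit_eval_single(tfidf_builder, mt$bdi_sum, mt$participant_id,
                            plan, space, "tfidf", diary_ids = mt$diary_id),
    timing_lexical = fit_eval_single(x_timing, mt$bdi_sum,
                                     mt$participant_id, plan, space,
                                     "timing_lexical"),
    audio_embedding = fit_eval_single(x_audio, mt$bdi_sum,
                                      mt$participant_id, plan, space,
                                      "audio_embedding"),
    dummy = dummy_regressor(mt$bdi_sum, mt$participant_id, plan,
                            diary_ids = mt$diary_id))
  res$fusion_text_tfidf <- stacked_fusion(
    list(text = x_text, tfidf = tfidf_builder), mt$bdi_sum,
    mt$participant_id, plan, space, "fusion_text_tfidf",
    diary_ids = mt$diary_id)
  leaderboard <- do.call(rbind, lapply(res, function(r) {
    data.frame(model = r$model, mae_mean = r$mae_mean, mae_sd = r$mae_sd,
               r2_mean = r$r2_mean, r2_sd = r$r2_sd,
               stringsAsFactors = FALSE)
  }))
  leaderboard <- leaderboard[order(leaderboard$mae_mean), ]
  utils::write.csv(leaderboard, file.path(out_dir, "leaderboard.csv"),
                   row.names = FALSE)
  utils::write.csv(res$text_embedding$predictions,
                   file.path(out_dir, "predictions_text.csv"),
                   row.names = FALSE)
  log_stage("benchmark", plan$seed)

  comps <- rbind(
    compare_models(res$text_embedding, res$dummy,
                   seed = substream_seed(seed, "cmp1")),
    compare_models(res$fusion_text_tfidf, res$text_embedding,
                   seed = substream_seed(seed, "cmp2")))
  utils::write.csv(comps, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  log_stage("comparisons", seed)

  calib <- calibration_report(res$text_embedding,
                              seed = substream_seed(seed, "calib"))
  jsonlite::write_json(calib, file.path(out_dir, "calibration_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  utils::write.csv(calib$bandwise, file.path(out_dir, "bandwise_errors.csv"),
                   row.names = FALSE)
  log_stage("calibration", seed)

  pert <- run_perturbation_study(cohort, text_provider,
                                 kinds = config$perturbation_kinds,
                                 plan = plan, space = space,
                                 seed = substream_seed(seed, "perturb"),
                                 n_perm = 1000)
  utils::write.csv(pert$results, file.path(out_dir, "perturbation_folds.csv"),
                   row.names = FALSE)
  utils::write.csv(pert$comparisons,
                   file.path(out_dir, "perturbation_table.csv"),
                   row.names = FALSE)
  log_stage("perturbations", substream_seed(seed, "perturb"))

  topics <- fit_topics(x_text, normalized_corpus(cohort, mt$diary_id),
                       target_k = config$topic_k)
  ts <- topic_bdi_summary(topics, mt)
  utils::write.csv(ts$table, file.path(out_dir, "topic_summary.csv"),
                   row.names = FALSE)
  items <- cohort_items_matrix(cohort, mt)
  tic <- topic_item_correlations(topics$probabilities, items)
  utils::write.csv(tic, file.path(out_dir, "topic_item_correlations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(keywords = topics$keywords,
                            theme_map = as.list(topics$theme_map),
                            kruskal = ts$kruskal),
                       file.path(out_dir, "topics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("topics", seed)

  invisible(list(cohort = cohort, plan = plan, results = res,
                 leaderboard = leaderboard, comparisons = comps,
                 calibration = calib, perturbation = pert,
                 topics = topics, topic_summary = ts))
}

#' TF-IDF builder refit on training partitions
#'
#' Returns a feature builder for [fit_eval_single()] that fits the TF-IDF
#' vocabulary and idf weights on the training diaries only, so no
#' document-frequency information leaks from test partitions.
#'
#' @param cohort a `voicebdi_cohort`.
#' @param ... passed to [tfidf_fit()].
#' @return function(train_ids, test_ids) -> list(train, test).
#' @export
make_tfidf_builder <- function(cohort, ...) {
  corp_all <- normalized_corpus(cohort)
  force(corp_all)
  args <- list(...)
  function(train_ids, test_ids) {
    model <- do.call(tfidf_fit, c(list(corp_all[train_ids]), args))
    list(train = tfidf_transform(model, corp_all[train_ids]),
         test = tfidf_transform(model, corp_all[test_ids]))
  }
}

#' BDI item matrix aligned to the modelling table
#'
#' @param cohort a `voicebdi_cohort`.
#' @param mt modelling table.
#' @return n x 21 integer matrix.
#' @export
cohort_items_matrix <- function(cohort, mt = modeling_table(cohort)) {
  paired <- pair_bdi(cohort$diaries, cohort$bdi)
  bid <- paired$paired_bdi_id[match(mt$diary_id, paired$diary_id)]
  m <- as.matrix(cohort$bdi[match(bid, cohort$bdi$bdi_id),
                            paste0("item_", 1:21)])
  rownames(m) <- mt$diary_id
  m
}
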