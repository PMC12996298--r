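#!/usr/bin/env Rscript
# Stage 5: topic layer.
#
# Clusters diary embeddings (PCA reduction + density clustering with
# outlier reassignment and a soft-assignment fallback), consolidates to six
# themes, labels them with cTF-IDF keywords and representative diaries, and
# relates themes to severity (Kruskal-Wallis omnibus, per-theme BDI table)
# and to the 21 BDI items (Spearman with Holm control within each theme).

suppressMessages(library(voicebdi))
seed <- as.integer(Sys.getenv("VOICEBDI_SEED", "1"))
out <- "results"

cohort <- generate_cohort(cohort_config(
  n_participants = 150, seed = substream_seed(seed, "topic_cohort"),
  adherence_log_mean = log(3), adherence_log_sd = 0.5,
  tokens_per_diary = 150))
mt <- modeling_table(cohort)
provider <- embedding_provider("topic", dim = 256,
                               seed = substream_seed(seed, "topic_emb"),
                               beta = 0, noise_sd = 0.05,
                               block_weights = c(3, 0.3, 0.3, 0.2))
x <- build_modality_matrix(cohort, provider, mt$diary_id)
tp <- fit_topics(x, normalized_corpus(cohort, mt$diary_id), target_k = 6,
                 min_cluster_size = 10)

ts <- topic_bdi_summary(tp, mt)
write.csv(ts$table, file.path(out, "topic_summary.csv"), row.names = FALSE)
items <- cohort_items_matrix(cohort, mt)
tic <- topic_item_correlations(tp$probabilities, items)
write.csv(tic, file.path(out, "topic_item_correlations.csv"),
          row.names = FALSE)
jsonlite::write_json(list(keywords = tp$keywords,
                          theme_map = as.list(tp$theme_map),
                          representatives = tp$representatives,
                          kruskal = ts$kruskal),
                     file.path(out, "topics.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("Per-theme BDI (ordered by mean):\n")
print(ts$table, row.names = FALSE)
cat(sprintf("\nKruskal-Wallis: H = %.1f, p = %.3g\n",
            ts$kruskal$H, ts$kruskal$p))
for (th in names(tp$keywords)) {
  cat("theme", th, ":", paste(head(tp$keywords[[th]], 6), collapse = ", "),
      "\n")
}
cat(sprintf("Holm-significant theme-item cells: %d of %d\n",
            sum(tic$significant, na.rm = TRUE), nrow(tic)))
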