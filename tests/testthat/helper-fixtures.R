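# Shared fixtures: small cohorts and token tables built in code.

small_cohort <- function(n = 40, seed = 42, ...) {
  generate_cohort(cohort_config(n_participants = n, seed = seed,
                                adherence_log_mean = log(3),
                                adherence_log_sd = 0.8, ...))
}

# A hand-built diary token table with known roles.
toy_tokens <- function() {
  data.frame(
    surface = c("Ich", "habe", "Gefühle", "gehabt", ".",
                "2021", "war", "Anna", "müde"),
    lemma = c("ich", "haben", "Gefühl", "haben", ".",
              "2021", "sein", "Anna", "müde"),
    role = c("function", "function", "content", "content", "punct",
             "numeral", "function", "proper_noun", "content"),
    sentence = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

# Synthetic predictions with known calibration: y = yhat + resid.
calib_predictions <- function(n = 500, resid_sd = 3, seed = 1) {
  withr::with_seed(seed, {
    y_pred <- runif(n, 0, 40)
    y_true <- y_pred + rnorm(n, 0, resid_sd)
    data.frame(diary_id = as.character(seq_len(n)), y_true = y_true,
               y_pred = y_pred, fold = rep(1:5, length.out = n))
  })
}
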