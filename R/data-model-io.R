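#' @name data_model_io
#' @title Core records, diary-BDI pairing, severity bands, cohort summaries
#'
#' @description
#' The diary/BDI pairing rule (temporally closest self-report within a
#' +/- 7 day window), the BDI severity bands, the summary statistics of a
#' cohort table, and plain-text readers/writers for the cohort files.
NULL

#' Pair diaries with the temporally closest BDI record
#'
#' Each diary is linked to the BDI record of the same participant that
#' minimises the absolute day difference, provided it falls within
#' `window_days`. Equidistant ties resolve to the earlier BDI (the
#' pre-diary state); one BDI may pair with several diaries. Timestamps are
#' compared at day resolution. Order-independent: shuffling the input rows
#' never changes a pairing.
#'
#' @param diaries data.frame with diary_id, participant_id, timestamp (Date).
#' @param bdi_records data.frame with bdi_id, participant_id, timestamp, sum.
#' @param window_days maximum |day difference| for a valid pair.
#' @return `diaries` with columns `paired_bdi_id`, `bdi_sum` and logical
#'   `paired`; unpaired diaries carry NA and `paired = FALSE`.
#' @export
pair_bdi <- function(diaries, bdi_records, window_days = 7) {
  stopifnot(all(c("diary_id", "participant_id", "timestamp") %in%
                  names(diaries)),
            all(c("bdi_id", "participant_id", "timestamp", "sum") %in%
                  names(bdi_records)))
  out <- diaries
  out$paired_bdi_id <- NA_character_
  out$bdi_sum <- NA_integer_
  bd <- bdi_records[order(bdi_records$timestamp, bdi_records$bdi_id), ]
  by_pid <- split(seq_len(nrow(bd)), bd$participant_id)
  d_day <- as.numeric(as.Date(out$timestamp))
  b_day <- as.numeric(as.Date(bd$timestamp))
  for (i in seq_len(nrow(out))) {
    idx <- by_pid[[out$participant_id[i]]]
    if (is.null(idx)) next
    dt <- abs(b_day[idx] - d_day[i])
    j <- idx[order(dt, b_day[idx])][1] # ties: earlier BDI wins
    if (abs(b_day[j] - d_day[i]) <= window_days) {
      out$paired_bdi_id[i] <- bd$bdi_id[j]
      out$bdi_sum[i] <- as.integer(bd$sum[j])
    }
  }
  out$paired <- !is.na(out$paired_bdi_id)
  out
}

.band_breaks <- c(0, 13, 19, 28, 63)
.band_labels <- c("minimal", "mild", "moderate", "severe")

#' Map a BDI sum to its severity band
#'
#' Bands partition 0-63: 0-13 minimal, 14-19 mild, 20-28 moderate,
#' 29 or higher severe.
#'
#' @param bdi_sum integer vector of BDI sums in 0..63.
#' @return factor with levels minimal, mild, moderate, severe.
#' @export
severity_band <- function(bdi_sum) {
  if (any(bdi_sum < 0 | bdi_sum > 63, na.rm = TRUE)) {
    stop("BDI sum out of range [0, 63]", call. = FALSE)
  }
  cut(bdi_sum, breaks = c(-0.5, 13.5, 19.5, 28.5, 63.5),
      labels = .band_labels)
}

#' Welch two-sample t statistic from summary statistics
#'
#' The canonical entry point takes group means, SDs and sizes (as printed in
#' a demographics table) rather than raw data.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, Welch-Satterthwaite `df`, and two-sided `p`.
#'   Zero pooled variance with equal means gives t = 0; with unequal means,
#'   a signed infinity with `degenerate = TRUE`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean1 - mean2) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Pearson chi-squared statistic for a 2x2 table
#'
#' Without continuity correction by default (large-sample setting); Yates
#' correction available as an option.
#'
#' @param counts 2x2 matrix of nonnegative counts with positive margins.
#' @param correct apply the Yates continuity correction.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi2_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi2_2x2: zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Cohort summary table
#'
#' Per-group and total counts, percentages, age and paired-BDI means (SD),
#' diaries-per-participant summaries, plus the Welch t statistics (age, BDI)
#' and the sex chi-squared. BDI statistics are at the sample (diary) level,
#' matching how longitudinal cohorts report "BDI at time of sample".
#'
#' @param cohort a `voicebdi_cohort` (the diary/BDI tables are paired
#'   internally if needed).
#' @param window_days pairing window in days.
#' @return list with data.frame `table` and list `tests`.
#' @export
cohort_summary <- function(cohort, window_days = 7) {
  pp <- cohort$participants
  paired <- pair_bdi(cohort$diaries, cohort$bdi, window_days)
  paired <- merge(paired, pp[, c("participant_id", "group")],
                  by = "participant_id")
  grp_stats <- function(g) {
    p <- pp[pp$group == g, ]
    d <- paired[paired$group == g & paired$paired, ]
    cnt <- table(factor(paired$participant_id[paired$group == g],
                        levels = p$participant_id))
    if (nrow(p) == 0) {
      return(data.frame(group = g, n_participants = 0L, pct_participants = NA,
                        n_samples = 0L, pct_female = NA, age_mean = NA,
                        age_sd = NA, bdi_mean = NA, bdi_sd = NA,
                        diaries_mean = NA, diaries_median = NA,
                        diaries_iqr_lo = NA, diaries_iqr_hi = NA))
    }
    q <- stats::quantile(as.numeric(cnt), c(0.25, 0.75), names = FALSE)
    data.frame(group = g,
               n_participants = nrow(p),
               pct_participants = 100 * nrow(p) / nrow(pp),
               n_samples = nrow(d),
               pct_female = 100 * mean(p$sex == "female"),
               age_mean = mean(p$age), age_sd = stats::sd(p$age),
               bdi_mean = mean(d$bdi_sum), bdi_sd = stats::sd(d$bdi_sum),
               diaries_mean = mean(as.numeric(cnt)),
               diaries_median = stats::median(as.numeric(cnt)),
               diaries_iqr_lo = q[1], diaries_iqr_hi = q[2])
  }
  tab <- rbind(grp_stats("HC"), grp_stats("MDD"), {
    t <- grp_stats("HC")
    all_d <- paired[paired$paired, ]
    cnt <- table(factor(paired$participant_id, levels = pp$participant_id))
    q <- stats::quantile(as.numeric(cnt), c(0.25, 0.75), names = FALSE)
    data.frame(group = "Total", n_participants = nrow(pp),
               pct_participants = 100,
               n_samples = nrow(all_d),
               pct_female = 100 * mean(pp$sex == "female"),
               age_mean = mean(pp$age), age_sd = stats::sd(pp$age),
               bdi_mean = mean(all_d$bdi_sum),
               bdi_sd = stats::sd(all_d$bdi_sum),
               diaries_mean = mean(as.numeric(cnt)),
               diaries_median = stats::median(as.numeric(cnt)),
               diaries_iqr_lo = q[1], diaries_iqr_hi = q[2])
  })
  hc <- tab[tab$group == "HC", ]
  md <- tab[tab$group == "MDD", ]
  tests <- list()
  if (hc$n_participants >= 2 && md$n_participants >= 2) {
    tests$age <- welch_t(hc$age_mean, hc$age_sd, hc$n_participants,
                         md$age_mean, md$age_sd, md$n_participants)
    if (hc$n_samples >= 2 && md$n_samples >= 2) {
      tests$bdi_sample_level <- welch_t(hc$bdi_mean, hc$bdi_sd, hc$n_samples,
                                        md$bdi_mean, md$bdi_sd, md$n_samples)
    }
    sex_tab <- table(pp$group, pp$sex)
    if (all(dim(sex_tab) == c(2, 2)) && all(rowSums(sex_tab) > 0) &&
        all(colSums(sex_tab) > 0)) {
      tests$sex <- chi2_2x2(sex_tab)
    }
  }
  list(table = tab, tests = tests)
}

# ---- File readers/writers --------------------------------------------------

#' Write / read a cohort as plain-text files
#'
#' A cohort is serialised as three UTF-8 files in `dir`: `diaries.jsonl`
#' (one diary per line with its role-tagged tokens), `bdi.csv`
#' (participant_id, timestamp, item_1..item_21, sum) and `participants.csv`.
#'
#' @param cohort a `voicebdi_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  con <- file(file.path(dir, "diaries.jsonl"), open = "w", encoding = "UTF-8")
  on.exit(close(con))
  tok_split <- split(cohort$tokens, cohort$tokens$diary_id)
  for (i in seq_len(nrow(cohort$diaries))) {
    d <- cohort$diaries[i, ]
    tk <- tok_split[[d$diary_id]]
    rec <- list(diary_id = d$diary_id,
                participant_id = d$participant_id,
                timestamp = format(as.Date(d$timestamp)),
                duration_s = d$duration_s,
                pause_s = d$pause_s,
                severity = if ("severity" %in% names(d)) d$severity else NULL,
                tokens = if (is.null(tk)) list() else
                  tk[, c("surface", "lemma", "role", "sentence")])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  bdi <- cohort$bdi
  bdi$timestamp <- format(as.Date(bdi$timestamp))
  utils::write.csv(
    bdi[, c("bdi_id", "participant_id", "timestamp",
            paste0("item_", 1:21), "sum")],
    file.path(dir, "bdi.csv"), row.names = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_cohort` returns a `voicebdi_cohort` (without latent
#'   trajectories, which are generator-internal).
#' @export
read_cohort <- function(dir) {
  lines <- readLines(file.path(dir, "diaries.jsonl"), encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON)
  diaries <- do.call(rbind, lapply(recs, function(r) {
    data.frame(diary_id = r$diary_id, participant_id = r$participant_id,
               timestamp = as.Date(r$timestamp), duration_s = r$duration_s,
               pause_s = r$pause_s,
               severity = if (is.null(r$severity)) NA_real_ else r$severity,
               stringsAsFactors = FALSE)
  }))
  tokens <- do.call(rbind, lapply(recs, function(r) {
    if (length(r$tokens) == 0) return(NULL)
    tk <- as.data.frame(r$tokens, stringsAsFactors = FALSE)
    tk$diary_id <- r$diary_id
    tk
  }))
  bdi <- utils::read.csv(file.path(dir, "bdi.csv"),
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  bdi$timestamp <- as.Date(bdi$timestamp)
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE,
                                  encoding = "UTF-8")
  structure(list(participants = participants, diaries = diaries,
                 tokens = tokens, bdi = bdi,
                 trajectories = NULL, theme_mixtures = NULL, config = NULL),
            class = "voicebdi_cohort")
}

#' Export the paired modelling table
#'
#' @param cohort a `voicebdi_cohort`.
#' @param path CSV destination.
#' @param window_days pairing window.
#' @return the table, invisibly.
#' @export
write_modeling_table <- function(cohort, path, window_days = 7) {
  paired <- pair_bdi(cohort$diaries, cohort$bdi, window_days)
  paired <- merge(paired,
                  cohort$participants[, c("participant_id", "group")],
                  by = "participant_id")
  tab <- paired[paired$paired,
                c("diary_id", "participant_id", "group", "bdi_sum",
                  "timestamp")]
  tab$band <- as.character(severity_band(tab$bdi_sum))
  tab <- tab[order(tab$diary_id),
             c("diary_id", "participant_id", "group", "bdi_sum", "band",
               "timestamp")]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
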