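#!/usr/bin/env Rscript
# Stage 3: calibration and agreement analysis of the best text model.
#
# Works on the concatenated out-of-fold predictions written by stage 2:
# calibration-in-the-large and slope, Bland-Altman bias and limits of
# agreement with bootstrap CIs, proportional bias, and per-severity-band
# errors. Residuals are observed minus predicted throughout.

suppressMessages(library(voicebdi))
seed <- as.integer(Sys.getenv("VOICEBDI_SEED", "1"))
out <- "results"
pred <- read.csv(file.path(out, "predictions_text.csv"))

rep <- calibration_report(pred, n_boot = 2000,
                          seed = substream_seed(seed, "calib"))
jsonlite::write_json(rep, file.path(out, "calibration_report.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE,
                     pretty = TRUE)
write.csv(rep$bandwise, file.path(out, "bandwise_errors.csv"),
          row.names = FALSE)

cat(sprintf("Calibration: intercept %.2f [%.2f, %.2f], slope %.2f [%.2f, %.2f]\n",
            rep$calibration$intercept, rep$calibration$intercept_ci[1],
            rep$calibration$intercept_ci[2], rep$calibration$slope,
            rep$calibration$slope_ci[1], rep$calibration$slope_ci[2]))
cat(sprintf("Bland-Altman: bias %+.2f, LoA (%.2f, %.2f)\n",
            rep$bland_altman$bias, rep$bland_altman$loa_lower,
            rep$bland_altman$loa_upper))
cat(sprintf("Proportional bias slope %.3f (p = %.3g)\n",
            rep$proportional_bias$slope, rep$proportional_bias$p))
print(rep$bandwise, row.names = FALSE)
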