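#!/usr/bin/env Rscript
# Stage 5: the instrumented levodopa challenge. For every subject:
# severity at dose time versus effect time, the absolute and percentage
# response, and the exclusion flags (uncertain zone, already ON, excess
# variability).

suppressPackageStartupMessages(library(wristldct))

out <- "results/analysis"
recordings <- read_epochs(file.path(out, "epochs.csv"),
                          file.path(out, "doses.json"),
                          file.path(out, "clinical.csv"))
model <- read_severity_model(file.path(out, "model.json"))

results <- run_ldct_cohort(recordings, model)
write.csv(results, file.path(out, "ldct_results.csv"), row.names = FALSE)

pw <- results[results$group == "PwP", ]
cat(sprintf("%d subjects, %d with both windows available\n", nrow(results),
            sum(results$reason == "ok")))
cat(sprintf("patient flags: %d uncertain, %d already ON, %d variable\n",
            sum(pw$flag_uncertain, na.rm = TRUE),
            sum(pw$flag_already_on, na.rm = TRUE),
            sum(pw$flag_variable_amplitude | pw$flag_variable_latency,
                na.rm = TRUE)))
cat(sprintf("mean absolute instrumented response (patients): %.2f levels\n",
            mean(pw$abs_delta_pkg, na.rm = TRUE)))
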