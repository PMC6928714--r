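#!/usr/bin/env Rscript
# Stage 2: activity labeling, dose/effect windows and epoch features.
# Every usable dose-time epoch is labeled with the subject's OFF-state
# severity level, every effect-time epoch with the ON-state level, and
# control epochs (nominal 07:00 dose time) with level 0.

suppressPackageStartupMessages(library(wristldct))

out <- "results/analysis"
recordings <- read_epochs(file.path(out, "epochs.csv"),
                          file.path(out, "doses.json"),
                          file.path(out, "clinical.csv"))

samples <- build_training_samples(recordings)
write.csv(samples, file.path(out, "feature_samples.csv"), row.names = FALSE)

cat(sprintf("%d usable window epochs from %d subjects\n", nrow(samples),
            length(unique(samples$subject_id))))
cat("epochs per severity level:\n")
print(table(samples$mfsl))
cat("epochs per role:\n")
print(table(samples$role))
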