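#!/usr/bin/env Rscript
# Stage 1: simulate a cohort of wrist-sensor recordings with known
# ground truth (60 patients, 60 controls, 6 days at 2-minute epochs) and
# write the epoch stream, dose events, clinical labels and truth table.
#
# The later stages (02-06) read these files back, so the whole analysis
# can be re-run file by file; `wristldct::run_pipeline()` performs the
# same sequence in one call.

suppressPackageStartupMessages(library(wristldct))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(n_pwp = 60, n_controls = 60, n_days = 6,
                         seed = 20260920)
cohort <- simulate_cohort(cfg)

write_epochs(cohort$recordings, file.path(out, "epochs.csv"),
             file.path(out, "doses.json"), file.path(out, "clinical.csv"))
write.csv(cohort$truth, file.path(out, "truth.csv"), row.names = FALSE)

tr <- cohort$truth
cat(sprintf("simulated %d patients + %d controls over %d days\n",
            sum(tr$group == "PwP"), sum(tr$group == "control"), cfg$n_days))
cat(sprintf("OFF UPDRS III: mean %.1f (SD %.1f); OFF-ON improvement: mean %.1f\n",
            mean(tr$updrs_off[tr$group == "PwP"]),
            sd(tr$updrs_off[tr$group == "PwP"]),
            mean((tr$updrs_off - tr$updrs_on)[tr$group == "PwP"])))
cat(sprintf("%d patients simulated as already ON\n", sum(tr$already_on)))
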