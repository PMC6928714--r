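#!/usr/bin/env Rscript
# Stage 4: train the bank of 5 threshold classifiers (L2 logistic
# regression, penalty tuned by 10-fold cross-validation) on a
# subject-grouped 70/30 split and report per-classifier ROC/PR AUC.

suppressPackageStartupMessages(library(wristldct))

out <- "results/analysis"
samples <- read.csv(file.path(out, "feature_samples.csv"))

model <- train_severity_model(samples, model_family = "logistic",
                              test_fraction = 0.30, cv_folds = 10,
                              seed = 404)
write.csv(model$training_report, file.path(out, "training_report.csv"),
          row.names = FALSE)
write_severity_model(model, file.path(out, "model.json"))

cat("per-classifier performance (cross-validated and held-out):\n")
print(model$training_report[, c("classifier", "threshold", "cv_roc_auc",
                                "cv_pr_auc", "test_roc_auc",
                                "test_pr_auc")],
      row.names = FALSE, digits = 3)
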