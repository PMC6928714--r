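#!/usr/bin/env Rscript
# Stage 3: feature relevance and redundancy. Mutual information of each
# candidate feature with the 6 severity classes (k-nearest-neighbour
# estimator, k = 6), then the greedy JMIM ranking of the refined set.
# The k-NN estimator is quadratic in the sample count, so a deterministic
# subsample of the window epochs is used.

suppressPackageStartupMessages(library(wristldct))

out <- "results/analysis"
samples <- read.csv(file.path(out, "feature_samples.csv"))

set.seed(303)
n_mi <- min(nrow(samples), 1500)
sub <- samples[sort(sample(nrow(samples), n_mi)), ]

feats <- intersect(selected_features(), names(sub))
mi_tab <- do.call(rbind, lapply(feats, function(f) {
  data.frame(feature = f,
             mi = mi_continuous_discrete(sub[[f]], sub$mfsl)$mi,
             k_neighbors = 6)
}))
write.csv(mi_tab, file.path(out, "mi_table.csv"), row.names = FALSE)

ranking <- jmim_rank(sub[, feats], sub$mfsl)
write.csv(ranking, file.path(out, "jmim_ranking.csv"), row.names = FALSE)

cat(sprintf("mutual information on %d epochs (nats):\n", n_mi))
print(mi_tab, row.names = FALSE)
cat("JMIM ranking:\n")
print(ranking, row.names = FALSE)
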