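#!/usr/bin/env Rscript
# Stage 6: classification performance of the instrumented response
# against the binary clinical response, under the cumulative exclusion
# scenarios (none; already ON; uncertain zone; both; plus excess
# variability).

suppressPackageStartupMessages(library(wristldct))

out <- "results/analysis"
results <- read.csv(file.path(out, "ldct_results.csv"))

tab <- rbind(cbind(score = "abs", scenario_table(results, "abs")),
             cbind(score = "pct", scenario_table(results, "pct")))
write.csv(tab, file.path(out, "scenario_table.csv"), row.names = FALSE)

cat("absolute response:\n")
print(tab[tab$score == "abs", -1], row.names = FALSE, digits = 3)
cat("percentage response:\n")
print(tab[tab$score == "pct", -1], row.names = FALSE, digits = 3)
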