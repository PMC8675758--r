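#!/usr/bin/env Rscript
# Stage 3: assemble per-resident centrality trajectories, compute the four
# hierarchy measures, and test the climb hypothesis: centrality in the
# last four weeks of tenure should sit below centrality over the whole
# tenure (a Wilcoxon signed-rank decline per resident).

suppressPackageStartupMessages(library(pullup))

out_dir <- "results/unit"
roster <- read_roster(file.path(out_dir, "roster.csv"))
cent <- read.csv(file.path(out_dir, "centrality.csv"))

summ <- summarize_all(cent)
write.csv(summ, file.path(out_dir, "hierarchy_summary.csv"), row.names = FALSE)

pairs <- paired_measures(summ)
w_max <- wilcoxon_signed_rank(pairs$max$overall, pairs$max$last_month,
                              alternative = "greater")
w_mean <- wilcoxon_signed_rank(pairs$mean$overall, pairs$mean$last_month,
                               alternative = "greater")

cat("Maximum centrality, overall vs last month:\n")
print(w_max)
cat("Mean centrality, overall vs last month:\n")
print(w_mean)
cat(sprintf("Mean of per-resident declines: max %.3f, mean %.3f\n",
            mean(pairs$max$overall - pairs$max$last_month),
            mean(pairs$mean$overall - pairs$mean$last_month)))

jsonlite::write_json(
  list(wilcoxon_max = list(V = w_max$V, z = w_max$z, p = w_max$p_value),
       wilcoxon_mean = list(V = w_mean$V, z = w_mean$z, p = w_mean$p_value)),
  file.path(out_dir, "wilcoxon.json"), auto_unbox = TRUE, digits = NA)
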