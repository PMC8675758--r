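#!/usr/bin/env Rscript
# Stage 1: simulate one therapeutic-community unit at the package's
# documented study scale (80 beds, 604 observation days) and write the two
# raw inputs every later stage consumes: the correction-event log and the
# resident roster. The latent ground truth (final ranks, graduation
# probabilities) is kept alongside for reference; no later stage reads it.

suppressPackageStartupMessages(library(pullup))

out_dir <- "results/unit"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
sim <- simulate_unit(cfg)

write_corrections(sim$events, file.path(out_dir, "corrections.csv"))
write_roster(sim$roster, file.path(out_dir, "roster.csv"))
jsonlite::write_json(
  list(config = unclass(cfg),
       final_rank = as.list(sim$truth$final_rank),
       graduation_probability = as.list(sim$truth$graduation_probability)),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated %d residents over %d days: %d corrections, graduation rate %.2f\n",
            nrow(sim$roster), cfg$span_days, nrow(sim$events),
            mean(sim$roster$graduated)))
cat("Wrote corrections.csv, roster.csv, truth.json to", out_dir, "\n")
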