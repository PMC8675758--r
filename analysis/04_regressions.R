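#!/usr/bin/env Rscript
# Stage 4: the graduation models. Four logistic regressions — one per
# hierarchy measure, each controlling for age, LSI-R, minority race and
# days in program — plus predicted-probability curves over each measure's
# observed range at mean covariates.

suppressPackageStartupMessages(library(pullup))

out_dir <- "results/unit"
roster <- read_roster(file.path(out_dir, "roster.csv"))
summ <- read.csv(file.path(out_dir, "hierarchy_summary.csv"))

res <- run_unit_analysis(summ, roster)
print(res)

jsonlite::write_json(results_to_list(res), file.path(out_dir, "results.json"),
                     auto_unbox = TRUE, digits = NA)

curves <- do.call(rbind, lapply(names(res$models), function(nm) {
  fit <- res$models[[nm]]
  if (!inherits(fit, "pullup_logit") || !fit$converged) return(NULL)
  grid <- seq(0, max(summ[[nm]]), length.out = 50)
  cbind(measure = nm, predicted_probability_curve(fit, nm, grid))
}))
write.csv(curves, file.path(out_dir, "predicted_probability_curves.csv"),
          row.names = FALSE)
cat("Wrote results.json and predicted_probability_curves.csv to", out_dir, "\n")
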