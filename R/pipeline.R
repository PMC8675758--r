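#' Run the full hierarchy-inference pipeline on one unit
#'
#' Ingest (files or simulator) -> validation -> weekly networks ->
#' eigenvector centrality -> trajectories -> hierarchy measures ->
#' Wilcoxon tests and the four graduation regressions. When `out_dir` is
#' given, all intermediate tables and a run manifest are written; a rerun
#' with an identical config reproduces them exactly.
#'
#' @param events_path,roster_path CSV inputs, or
#' @param sim A [sim_config()] to generate a synthetic unit instead
#'   (exactly one input source must be supplied).
#' @param epsilon,tol,max_iter Centrality parameters, see
#'   [eigenvector_centrality()].
#' @param binary_edges Collapse repeated same-pair weekly corrections.
#' @param min_weeks Minimum scored weeks for inclusion in the summary
#'   table (0 keeps all residents).
#' @param out_dir Optional output directory for artifacts.
#' @return A `pullup_unit_results` with extra fields: `summaries`,
#'   `validation`, `n_windows`.
#' @export
run_pipeline <- function(events_path = NULL, roster_path = NULL, sim = NULL,
                         epsilon = 1e-4, tol = 1e-12, max_iter = 200L,
                         binary_edges = FALSE, min_weeks = 0L,
                         out_dir = NULL) {
  from_files <- !is.null(events_path) || !is.null(roster_path)
  if (from_files == !is.null(sim)) {
    stop("supply exactly one input source: events/roster paths xor a sim config")
  }
  if (from_files) {
    events <- read_corrections(events_path)
    roster <- read_roster(roster_path)
  } else {
    unit <- simulate_unit(sim)
    events <- unit$events
    roster <- unit$roster
  }

  validation <- cross_validate(events, roster)
  windows <- make_week_windows(min(roster$entry_date), max(roster$exit_date))
  networks <- build_all_networks(validation$events, roster, windows,
                                 binary_edges)
  weekly_scores <- centrality_over_windows(networks, epsilon, tol, max_iter)
  trajectories <- build_trajectories(weekly_scores, roster)
  summaries <- summarize_all(trajectories, min_weeks)
  results <- run_unit_analysis(summaries, roster)

  results$summaries <- summaries
  results$validation <- validation$report
  results$n_windows <- nrow(windows)

  if (!is.null(out_dir)) {
    write_pipeline_artifacts(out_dir, validation, networks, weekly_scores,
                             summaries, results,
                             config = list(epsilon = epsilon, tol = tol,
                                           max_iter = max_iter,
                                           binary_edges = binary_edges,
                                           min_weeks = min_weeks,
                                           sim = if (!from_files) unclass(sim)))
  }
  results
}

write_pipeline_artifacts <- function(out_dir, validation, networks,
                                     weekly_scores, summaries, results,
                                     config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_validation_report(validation, file.path(out_dir, "validation.json"))
  utils::write.csv(networks_to_edgelist(networks),
                   file.path(out_dir, "weekly_edges.csv"), row.names = FALSE)
  utils::write.csv(centrality_to_table(weekly_scores),
                   file.path(out_dir, "centrality.csv"), row.names = FALSE)
  utils::write.csv(summaries, file.path(out_dir, "hierarchy_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(results_to_list(results),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(utils::capture.output(print(results)),
             file.path(out_dir, "results.txt"))
  manifest <- list(package_version = as.character(utils::packageVersion("pullup")),
                   config = config, warnings = results$warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Flatten unit results to plain lists for JSON serialisation
#' @param results A `pullup_unit_results`.
#' @return Nested plain list.
#' @export
results_to_list <- function(results) {
  wil <- function(w) {
    if (inherits(w, "pullup_wilcoxon")) {
      list(V = w$V, z = w$z, p_value = w$p_value, n_pairs = w$n_pairs,
           n_nonzero = w$n_nonzero)
    } else w
  }
  mods <- lapply(results$models, function(m) {
    if (inherits(m, "pullup_logit")) {
      list(coefficients = m$coefficients, log_likelihood = m$log_likelihood,
           deviance = m$deviance, aic = m$aic, bic = m$bic, n = m$n,
           converged = m$converged)
    } else m
  })
  list(descriptives = results$descriptives,
       wilcoxon_max = wil(results$wilcoxon_max),
       wilcoxon_mean = wil(results$wilcoxon_mean),
       models = mods, n_complete = results$n_complete,
       warnings = results$warnings)
}
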