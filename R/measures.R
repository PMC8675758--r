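#' Assemble per-resident centrality trajectories
#'
#' A resident's trajectory is their weekly centrality score over every
#' window that overlaps their tenure — including correction-free weeks,
#' where the score is the epsilon-floor value, so per-resident means over
#' tenure are well defined.
#'
#' @param weekly_scores List of `pullup_centrality` covering the span.
#' @param roster Roster data frame.
#' @return Data frame `resident_id`, `window_index`, `score`, ordered by
#'   resident then window. Residents overlapping no window are excluded
#'   with a warning.
#' @export
build_trajectories <- function(weekly_scores, roster) {
  tab <- centrality_to_table(weekly_scores)
  tab <- tab[order(tab$resident_id, tab$window_index), , drop = FALSE]
  missing <- setdiff(roster$resident_id, tab$resident_id)
  if (length(missing)) {
    warning(length(missing), " resident(s) overlap no scored window; excluded")
  }
  tab <- tab[tab$resident_id %in% roster$resident_id, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Four hierarchy measures from one trajectory
#'
#' Maximum and mean eigenvector centrality over the full tenure capture the
#' lowest hierarchy position a resident ever occupies and their average
#' position; the last-month variants restrict to the final four
#' week-windows of tenure (residents with fewer than four weeks use their
#' whole tenure). Because centrality is inversely related to hierarchy
#' standing, a drop from the overall to the last-month measure is a climb.
#'
#' @param scores Numeric centrality scores ordered by window.
#' @return One-row data frame: `max_ec`, `mean_ec`, `lm_max_ec`,
#'   `lm_mean_ec`, `n_weeks`, `n_lm_weeks`.
#' @export
summarize_hierarchy <- function(scores) {
  n <- length(scores)
  if (n < 1) stop("empty trajectory")
  n_lm <- min(4L, n)
  lm_scores <- scores[(n - n_lm + 1):n]
  data.frame(max_ec = max(scores), mean_ec = mean(scores),
             lm_max_ec = max(lm_scores), lm_mean_ec = mean(lm_scores),
             n_weeks = n, n_lm_weeks = n_lm)
}

#' Hierarchy summary table for all residents
#'
#' @param trajectories Long data frame from [build_trajectories()].
#' @param min_weeks Residents with fewer scored weeks are dropped (0 keeps
#'   all; sensitivity knob for excluding very short stays).
#' @return Data frame with `resident_id` and the [summarize_hierarchy()]
#'   columns, one row per resident, in roster (input) order.
#' @export
summarize_all <- function(trajectories, min_weeks = 0L) {
  ids <- unique(trajectories$resident_id)
  rows <- lapply(ids, function(id) {
    tr <- trajectories[trajectories$resident_id == id, , drop = FALSE]
    tr <- tr[order(tr$window_index), , drop = FALSE]
    if (nrow(tr) < min_weeks) return(NULL)
    cbind(data.frame(resident_id = id), summarize_hierarchy(tr$score))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired overall vs last-month samples for the signed-rank stage
#'
#' @param summaries Output of [summarize_all()].
#' @return List with elements `max` and `mean`, each a list of paired
#'   vectors `overall` and `last_month` in summary (roster) order.
#' @export
paired_measures <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  list(max = list(overall = summaries$max_ec,
                  last_month = summaries$lm_max_ec),
       mean = list(overall = summaries$mean_ec,
                   last_month = summaries$lm_mean_ec))
}
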