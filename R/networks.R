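#' Partition an observation span into one-week windows
#'
#' Daily correction data are aggregated into week-long blocks to remove
#' weekly periodicity (meeting schedules, visiting days). Windows are
#' half-open `[start, start + 7d)`, tile the span without overlap, and are
#' anchored at `span_start`; window `k` (0-based) starts at
#' `span_start + 7k` days.
#'
#' @param span_start,span_end First and last calendar date of observation.
#' @return Data frame with columns `index` (0-based), `start`, `end`
#'   (exclusive); `ceil((span_end - span_start + 1) / 7)` rows.
#' @export
make_week_windows <- function(span_start, span_end) {
  span_start <- as.Date(span_start)
  span_end <- as.Date(span_end)
  if (span_end < span_start) stop("reversed span: span_end precedes span_start")
  n_days <- as.numeric(span_end - span_start) + 1
  n_win <- ceiling(n_days / 7)
  idx <- seq_len(n_win) - 1L
  data.frame(index = idx,
             start = span_start + 7 * idx,
             end = span_start + 7 * (idx + 1))
}

#' Build the weighted directed correction network for one week
#'
#' Nodes are all residents whose tenure `[entry_date, exit_date]` overlaps
#' the window — including residents who neither sent nor received a
#' correction that week, so that a centrality score exists for every week
#' of every tenure. Entry `W[s, r]` counts the corrections sender `s` gave
#' receiver `r` during the window.
#'
#' @param events Validated corrections (from [cross_validate()]).
#' @param roster Roster data frame.
#' @param window One row of [make_week_windows()] output (or a list with
#'   `index`, `start`, `end`).
#' @param binary_edges Collapse repeated same-pair corrections within the
#'   week to weight 1 (sensitivity variant). Default `FALSE`: weights
#'   accumulate.
#' @return List of class `pullup_weekly_network`: `window`, `nodes`
#'   (resident ids), `W` (named square integer matrix, zero diagonal).
#' @export
build_weekly_network <- function(events, roster, window, binary_edges = FALSE) {
  start <- as.Date(window$start)
  end <- as.Date(window$end)
  present <- roster$entry_date < end & roster$exit_date >= start
  nodes <- roster$resident_id[present]

  in_win <- events$date >= start & events$date < end
  ev <- events[in_win, , drop = FALSE]

  W <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(ev)) {
    s <- match(ev$sender_id, nodes)
    r <- match(ev$receiver_id, nodes)
    if (anyNA(s) || anyNA(r)) {
      stop("event in window references a resident not present that week; ",
           "run cross_validate() first")
    }
    for (i in seq_along(s)) W[s[i], r[i]] <- W[s[i], r[i]] + 1L
    if (binary_edges) W[W > 0L] <- 1L
  }
  structure(list(window = list(index = window$index, start = start, end = end),
                 nodes = nodes, W = W),
            class = "pullup_weekly_network")
}

#' Build weekly networks for every window of a span
#'
#' @inheritParams build_weekly_network
#' @param windows Output of [make_week_windows()]; defaults to windows
#'   spanning the roster's earliest entry to latest exit.
#' @return List of `pullup_weekly_network`, one per window.
#' @export
build_all_networks <- function(events, roster, windows = NULL,
                               binary_edges = FALSE) {
  if (is.null(windows)) {
    windows <- make_week_windows(min(roster$entry_date), max(roster$exit_date))
  }
  lapply(seq_len(nrow(windows)), function(i) {
    build_weekly_network(events, roster, windows[i, ], binary_edges)
  })
}

#' Export weekly networks as a long edge list
#'
#' @param networks List of weekly networks.
#' @return Data frame `window_index`, `sender_id`, `receiver_id`, `weight`
#'   (positive-weight edges only).
#' @export
networks_to_edgelist <- function(networks) {
  parts <- lapply(networks, function(net) {
    nz <- which(net$W > 0L, arr.ind = TRUE)
    if (!nrow(nz)) return(NULL)
    data.frame(window_index = net$window$index,
               sender_id = net$nodes[nz[, 1]],
               receiver_id = net$nodes[nz[, 2]],
               weight = net$W[nz])
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(window_index = integer(0), sender_id = character(0),
                      receiver_id = character(0), weight = integer(0))
  }
  rownames(out) <- NULL
  out
}
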