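#' Read correction events from CSV
#'
#' A correction ("pull-up") is a dated, written piece of corrective peer
#' feedback; each record is one directed edge, sender to receiver. Rows
#' that cannot form a valid edge (unparseable date, missing id, sender
#' equal to receiver) are dropped and counted under a named reason rather
#' than silently discarded.
#'
#' @param path Path to a headered CSV file.
#' @param dialect Named character vector mapping the canonical column names
#'   `date`, `sender_id`, `receiver_id` to the column names used in the
#'   file. Defaults to the identity mapping.
#' @return A data frame of class `pullup_corrections` with columns `date`
#'   (`Date`), `sender_id`, `receiver_id` (character), carrying a
#'   `drop_report` attribute: a data frame of (reason, count) pairs for the
#'   rows removed.
#' @export
read_corrections <- function(path, dialect = NULL) {
  dialect <- resolve_dialect(dialect, c("date", "sender_id", "receiver_id"))
  raw <- read_table_file(path, dialect)
  n_read <- nrow(raw)
  drops <- character(0)

  date <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
  sender <- trimws(as.character(raw$sender_id))
  receiver <- trimws(as.character(raw$receiver_id))

  bad_date <- is.na(date)
  bad_id <- !bad_date & (is.na(sender) | is.na(receiver) | sender == "" | receiver == "")
  self_loop <- !bad_date & !bad_id & sender == receiver
  drops <- c(rep("unparseable_date", sum(bad_date)),
             rep("missing_id", sum(bad_id)),
             rep("self_loop", sum(self_loop)))

  keep <- !(bad_date | bad_id | self_loop)
  out <- data.frame(date = date[keep], sender_id = sender[keep],
                    receiver_id = receiver[keep], stringsAsFactors = FALSE)
  class(out) <- c("pullup_corrections", class(out))
  attr(out, "n_read") <- n_read
  attr(out, "drop_report") <- tabulate_reasons(drops)
  out
}

#' Write correction events to CSV
#'
#' Inverse of [read_corrections()]: writing then re-reading yields an
#' identical event table.
#'
#' @param events Corrections data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corrections <- function(events, path) {
  df <- data.frame(date = format(events$date, "%Y-%m-%d"),
                   sender_id = events$sender_id,
                   receiver_id = events$receiver_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the resident roster from CSV
#'
#' One row per resident: entry and exit dates, graduation indicator, age,
#' a binary minority-race indicator, and the LSI-R recidivism-risk score.
#' `days_in_program` is derived as `exit_date - entry_date` in days.
#' Residents with a missing covariate are kept but flagged `incomplete`;
#' the regression stage excludes them.
#'
#' @param path Path to a headered CSV file.
#' @param dialect Named character vector mapping canonical names
#'   (`resident_id`, `entry_date`, `exit_date`, `graduated`, `age`,
#'   `race_minority`, `lsi_r`) to file column names.
#' @return A data frame of class `pullup_roster` with the canonical columns
#'   plus `days_in_program` and logical `incomplete`.
#' @export
read_roster <- function(path, dialect = NULL) {
  cols <- c("resident_id", "entry_date", "exit_date", "graduated",
            "age", "race_minority", "lsi_r")
  dialect <- resolve_dialect(dialect, cols)
  raw <- read_table_file(path, dialect)

  id <- trimws(as.character(raw$resident_id))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate resident_id in roster: ", paste(dup, collapse = ", "))
  }
  entry <- as.Date(as.character(raw$entry_date), format = "%Y-%m-%d")
  exit <- as.Date(as.character(raw$exit_date), format = "%Y-%m-%d")
  if (anyNA(entry) || anyNA(exit)) {
    stop("unparseable entry/exit date at roster row(s) ",
         paste(which(is.na(entry) | is.na(exit)), collapse = ", "))
  }
  rev_rows <- which(exit < entry)
  if (length(rev_rows)) {
    stop("exit_date before entry_date at roster row(s) ",
         paste(rev_rows, collapse = ", "))
  }

  grad <- suppressWarnings(as.integer(raw$graduated))
  if (any(!is.na(grad) & !grad %in% c(0L, 1L))) {
    stop("graduated must be 0/1")
  }
  age <- suppressWarnings(as.numeric(raw$age))
  race <- suppressWarnings(as.integer(raw$race_minority))
  lsi <- suppressWarnings(as.numeric(raw$lsi_r))
  if (any(!is.na(lsi) & lsi < 0)) stop("lsi_r must be >= 0")

  incomplete <- is.na(grad) | is.na(age) | is.na(race) | is.na(lsi)
  if (any(incomplete)) {
    warning(sum(incomplete), " resident(s) with missing covariates flagged ",
            "incomplete; they are excluded from the regression stage")
  }

  out <- data.frame(resident_id = id, entry_date = entry, exit_date = exit,
                    graduated = grad, age = age, race_minority = race,
                    lsi_r = lsi,
                    days_in_program = as.numeric(exit - entry),
                    incomplete = incomplete, stringsAsFactors = FALSE)
  class(out) <- c("pullup_roster", class(out))
  out
}

#' Write a roster to CSV
#' @param roster Roster data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  df <- data.frame(resident_id = roster$resident_id,
                   entry_date = format(roster$entry_date, "%Y-%m-%d"),
                   exit_date = format(roster$exit_date, "%Y-%m-%d"),
                   graduated = roster$graduated,
                   age = roster$age,
                   race_minority = roster$race_minority,
                   lsi_r = roster$lsi_r)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check correction events against the roster
#'
#' Drops events whose sender or receiver is not on the roster
#' (`unknown_resident`) or whose date falls outside either participant's
#' tenure window (`out_of_tenure`; archival boundary noise, not treated as
#' fatal). Idempotent: a second pass over the surviving events drops
#' nothing.
#'
#' @param events Corrections data frame from [read_corrections()].
#' @param roster Roster data frame from [read_roster()].
#' @return A list of class `pullup_validation`: `events` (the surviving
#'   corrections) and `report` with `n_events_read`, `n_events_dropped`,
#'   `drop_reasons` (data frame of reason/count) and `n_residents`.
#' @export
cross_validate <- function(events, roster) {
  n_in <- nrow(events)
  idx <- match(events$sender_id, roster$resident_id)
  ridx <- match(events$receiver_id, roster$resident_id)
  unknown <- is.na(idx) | is.na(ridx)

  ok_sender <- rep(FALSE, n_in)
  ok_receiver <- rep(FALSE, n_in)
  known <- which(!unknown)
  if (length(known)) {
    ok_sender[known] <- events$date[known] >= roster$entry_date[idx[known]] &
      events$date[known] <= roster$exit_date[idx[known]]
    ok_receiver[known] <- events$date[known] >= roster$entry_date[ridx[known]] &
      events$date[known] <= roster$exit_date[ridx[known]]
  }
  out_of_tenure <- !unknown & !(ok_sender & ok_receiver)

  reasons <- c(rep("unknown_resident", sum(unknown)),
               rep("out_of_tenure", sum(out_of_tenure)))
  # carry forward reasons recorded at parse time, if any
  parse_drops <- attr(events, "drop_report")
  keep <- !(unknown | out_of_tenure)
  surviving <- events[keep, , drop = FALSE]
  rownames(surviving) <- NULL
  class(surviving) <- class(events)

  report <- list(
    n_events_read = if (!is.null(attr(events, "n_read"))) attr(events, "n_read") else n_in,
    n_events_in = n_in,
    n_events_dropped = sum(!keep),
    n_events_kept = sum(keep),
    drop_reasons = merge_reasons(parse_drops, tabulate_reasons(reasons)),
    n_residents = nrow(roster)
  )
  structure(list(events = surviving, report = report),
            class = "pullup_validation")
}

#' @export
print.pullup_validation <- function(x, ...) {
  r <- x$report
  cat("Correction-event validation\n")
  cat("  events in:     ", r$n_events_in, "\n")
  cat("  events kept:   ", r$n_events_kept, "\n")
  cat("  events dropped:", r$n_events_dropped, "\n")
  if (nrow(r$drop_reasons)) {
    for (i in seq_len(nrow(r$drop_reasons))) {
      cat("    ", r$drop_reasons$reason[i], ":", r$drop_reasons$count[i], "\n")
    }
  }
  cat("  residents:     ", r$n_residents, "\n")
  invisible(x)
}

#' Write a validation report as JSON
#' @param validation Result of [cross_validate()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(validation, path) {
  jsonlite::write_json(validation$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

resolve_dialect <- function(dialect, canonical) {
  full <- stats::setNames(canonical, canonical)
  if (is.null(dialect)) return(full)
  stopifnot(is.character(dialect), !is.null(names(dialect)))
  unknown <- setdiff(names(dialect), canonical)
  if (length(unknown)) stop("unknown dialect keys: ", paste(unknown, collapse = ", "))
  full[names(dialect)] <- dialect
  full
}

read_table_file <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- dialect[!dialect %in% names(raw)]
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- raw[, dialect, drop = FALSE]
  names(out) <- names(dialect)
  out
}

tabulate_reasons <- function(reasons) {
  if (!length(reasons)) {
    return(data.frame(reason = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(reasons)
  data.frame(reason = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

merge_reasons <- function(a, b) {
  if (is.null(a) || !nrow(a)) return(b)
  if (is.null(b) || !nrow(b)) return(a)
  m <- rbind(a, b)
  agg <- stats::aggregate(count ~ reason, data = m, FUN = sum)
  agg[order(agg$reason), , drop = FALSE]
}
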