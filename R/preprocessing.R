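#' Remove check-ins at rarely visited POIs
#'
#' Drops every record whose POI has fewer than `min_count` check-ins,
#' counting on the INPUT collection in a single pass (no re-iteration after
#' removal). Rarely used POIs are a common source of noise — mis-taps and
#' invalid locations — in check-in streams.
#'
#' @param records check-in tibble.
#' @param min_count minimum check-ins a POI needs for its records to
#'   survive (default 10).
#' @return filtered records, input order preserved.
#' @export
filter_low_activity_pois <- function(records, min_count = 10L) {
  if (!is.numeric(min_count) || min_count < 1L) {
    stop("min_count must be a positive integer", call. = FALSE)
  }
  counts <- table(records$poi_id)
  keep <- counts[records$poi_id] >= min_count
  records[as.vector(keep), ]
}

#' Remove rapid-fire repeat check-ins
#'
#' Per user, scans records in time order and keeps a record only if its
#' timestamp is at least `min_gap_minutes` after the LAST KEPT record of
#' that user (greedy keep-first; the first record per user is always kept).
#' Users are filtered independently of one another. Ties in time are broken
#' by input order (stable sort) for reproducibility.
#'
#' @param records check-in tibble with parsed timestamps.
#' @param min_gap_minutes minimum spacing between kept check-ins of one
#'   user (default 10).
#' @return filtered records, original input order preserved among
#'   survivors.
#' @export
filter_short_intervals <- function(records, min_gap_minutes = 10) {
  if (nrow(records) == 0L) return(records)
  min_gap <- min_gap_minutes * 60
  keep <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), records$user_id)) {
    idx <- idx[order(records$timestamp[idx])]  # stable: ties keep input order
    last_kept <- -Inf
    for (i in idx) {
      t_i <- as.numeric(records$timestamp[i])
      if (t_i - last_kept >= min_gap || !is.finite(last_kept)) {
        keep[i] <- TRUE
        last_kept <- t_i
      }
    }
  }
  records[keep, ]
}

#' Assign each record to its 5 AM-anchored day
#'
#' A record at wall-clock time t belongs to the half-open window
#' `[boundary_hour:00, boundary_hour:00 + 24h)` starting at the most recent
#' boundary at or before t; the window is labeled by the calendar date of
#' its start (`day_anchor`). 5 AM is the default boundary because check-in
#' activity is at its daily minimum then, so windows align with waking days
#' rather than calendar days.
#'
#' @param records check-in tibble.
#' @param boundary_hour hour of day (0-23) at which days are cut.
#' @return the records with a `day_anchor` (`Date`) column added.
#' @export
segment_days <- function(records, boundary_hour = 5L) {
  stopifnot(boundary_hour >= 0L, boundary_hour <= 23L)
  records$day_anchor <- as.Date(records$timestamp - boundary_hour * 3600,
                                tz = "UTC")
  records
}

#' Build merged daily activity-type sequences
#'
#' Within each (user, day) group, records are time-sorted and consecutive
#' runs of the same activity type are collapsed to a single item stamped
#' with the run's first timestamp; groups whose merged length is below
#' `min_length` are dropped (a single activity has no transition to study).
#' The result is the unit of all downstream counting: one row per daily
#' sequence, with the merged one-letter type codes as a list-column.
#'
#' @param records typed, day-segmented check-in tibble (see
#'   [assign_activity_types()], [segment_days()]).
#' @param min_length minimum merged sequence length to keep (default 2).
#' @return tibble with columns `user_id`, `day_anchor`, `types` (list of
#'   one-letter code vectors), `length`; attribute `stats` carries the
#'   pre/post filtering bookkeeping (see [sequence_stats()]).
#' @export
build_daily_sequences <- function(records, min_length = 2L) {
  if (is.null(records$day_anchor)) {
    stop("records must be day-segmented first; run segment_days()",
         call. = FALSE)
  }
  if (anyNA(records$activity_type)) {
    stop("records must be typed first; run assign_activity_types()",
         call. = FALSE)
  }
  groups <- split(seq_len(nrow(records)),
                  list(user = records$user_id,
                       day = as.character(records$day_anchor)),
                  drop = TRUE)
  rows <- lapply(groups, function(idx) {
    idx <- idx[order(records$timestamp[idx])]
    codes <- type_to_code(records$activity_type[idx])
    run_start <- c(TRUE, codes[-1L] != codes[-length(codes)])
    list(user_id = records$user_id[idx[1L]],
         day_anchor = records$day_anchor[idx[1L]],
         types = codes[run_start],
         first_ts = records$timestamp[idx[run_start]])
  })
  rows <- unname(rows)
  seqs <- tibble::tibble(
    user_id = vapply(rows, function(r) r$user_id, ""),
    day_anchor = as.Date(vapply(rows, function(r) as.character(r$day_anchor), "")),
    types = lapply(rows, function(r) r$types),
    first_ts = lapply(rows, function(r) r$first_ts),
    length = vapply(rows, function(r) length(r$types), 0L)
  )
  seqs <- seqs[order(seqs$user_id, seqs$day_anchor), ]
  n_raw <- nrow(seqs)
  kept <- seqs[seqs$length >= min_length, ]
  stats <- list(
    n_raw_sequences = n_raw,
    n_sequences = nrow(kept),
    n_users = length(unique(kept$user_id)),
    length_histogram = as.list(table(kept$length))
  )
  attr(kept, "stats") <- stats
  kept
}

#' Summary statistics of a daily-sequence table
#'
#' @param sequences tibble from [build_daily_sequences()].
#' @return list with sequence count, user count, and counts of sequences
#'   with length at least 2, 3, 4 and 5 (i.e. at least 1-4 transitions).
#' @export
sequence_stats <- function(sequences) {
  lens <- sequences$length
  list(
    n_sequences = length(lens),
    n_users = length(unique(sequences$user_id)),
    n_by_min_transitions = stats::setNames(
      vapply(1:4, function(k) sum(lens >= k + 1L), 0L),
      paste0("ge_", 1:4)
    ),
    length_histogram = as.list(table(lens))
  )
}

# Transition list of one sequence: character vector of "X>Y" edge codes.
sequence_transitions <- function(types) {
  k <- length(types)
  if (k < 2L) return(character())
  paste0(types[-k], ">", types[-1L])
}

#' Write / read a daily-sequence table
#'
#' One row per sequence: `user_id`, `day_anchor`, comma-joined type codes,
#' `length`. Round trips losslessly.
#'
#' @param sequences tibble from [build_daily_sequences()].
#' @param path CSV path.
#' @return `write_sequences()`: the path, invisibly; `read_sequences()`:
#'   the sequence tibble.
#' @export
write_sequences <- function(sequences, path) {
  out <- tibble::tibble(
    user_id = sequences$user_id,
    day_anchor = sequences$day_anchor,
    types = vapply(sequences$types, paste, "", collapse = ","),
    length = sequences$length
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    user_id = readr::col_character(),
    day_anchor = readr::col_date(),
    types = readr::col_character(),
    length = readr::col_integer()
  ), progress = FALSE)
  tibble::tibble(
    user_id = raw$user_id,
    day_anchor = raw$day_anchor,
    types = strsplit(raw$types, ",", fixed = TRUE),
    length = raw$length
  )
}

#' Run the full preprocessing pipeline
#'
#' Chains the cleaning stages in their fixed order: POI filter (counts on
#' the raw input), short-interval filter, activity-type assignment, day
#' segmentation, run-merged sequence construction with the minimum-length
#' filter. Per-stage record counts are reported via `message()` so runs can
#' be audited against a dataset's published totals.
#'
#' @param records raw check-in tibble from [read_checkins()].
#' @param map category map tibble.
#' @param min_poi_checkins,min_interval_minutes,boundary_hour,min_length
#'   stage parameters (defaults 10, 10, 5, 2).
#' @param default_policy unmapped-category policy, see
#'   [assign_activity_types()].
#' @param quiet suppress stage-count messages.
#' @return daily-sequence tibble (see [build_daily_sequences()]); attribute
#'   `counts` holds the per-stage record totals.
#' @export
preprocess_checkins <- function(records, map = read_category_map(),
                                min_poi_checkins = 10L,
                                min_interval_minutes = 10,
                                boundary_hour = 5L,
                                min_length = 2L,
                                default_policy = "drop",
                                quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  counts <- list(raw = nrow(records))
  say("raw records: ", counts$raw)
  records <- filter_low_activity_pois(records, min_poi_checkins)
  counts$after_poi_filter <- nrow(records)
  say("after POI filter (min ", min_poi_checkins, " check-ins): ",
      counts$after_poi_filter)
  records <- filter_short_intervals(records, min_interval_minutes)
  counts$after_interval_filter <- nrow(records)
  say("after interval filter (min ", min_interval_minutes, " min): ",
      counts$after_interval_filter)
  if (anyNA(records$activity_type)) {
    records <- assign_activity_types(records, map,
                                     default_policy = default_policy)
  }
  counts$after_typing <- nrow(records)
  records <- segment_days(records, boundary_hour)
  seqs <- build_daily_sequences(records, min_length = min_length)
  st <- attr(seqs, "stats")
  counts$raw_sequences <- st$n_raw_sequences
  counts$kept_sequences <- st$n_sequences
  say("daily sequences: ", counts$raw_sequences,
      "; kept (length >= ", min_length, "): ", counts$kept_sequences,
      " from ", st$n_users, " users")
  attr(seqs, "counts") <- counts
  seqs
}
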