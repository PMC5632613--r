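#' Export displacement events for dominance analysis
#'
#' Dominance-hierarchy tools consume either a chronological
#' winner/loser sequence (Elo-style scores) or a square interaction
#' matrix (David's scores, average dominance indices, network ranks).
#' The displacer is scored as the winner, the displacee as the loser.
#'
#' @param d Displacement table from [displacements()].
#' @return A `perch_interactions` object: list with `sequence` (tibble
#'   `time`, `winner`, `loser`, ordered by the displacer's start time)
#'   and `matrix` (square counts, rows = winners, columns = losers,
#'   animals in identical lexicographic order on both axes, zero
#'   diagonal).
#' @export
export_interactions <- function(d) {
  require_columns(d, c("displacer", "displacee", "displacer_start"),
    what = "displacement table")
  d <- arrange(as_tibble(d), .data$displacer_start)
  seq_tbl <- tibble(
    time = d$displacer_start,
    winner = as.character(d$displacer),
    loser = as.character(d$displacee)
  )
  animals <- sort(unique(c(seq_tbl$winner, seq_tbl$loser)))
  mat <- matrix(0L, nrow = length(animals), ncol = length(animals),
    dimnames = list(winner = animals, loser = animals))
  for (i in seq_len(nrow(seq_tbl))) {
    mat[seq_tbl$winner[i], seq_tbl$loser[i]] <-
      mat[seq_tbl$winner[i], seq_tbl$loser[i]] + 1L
  }
  structure(list(sequence = seq_tbl, matrix = mat),
    class = "perch_interactions")
}

#' @export
print.perch_interactions <- function(x, ...) {
  cat(sprintf("<interactions> %d events, %d animals\n",
    nrow(x$sequence), nrow(x$matrix)))
  invisible(x)
}

#' Export detections as an event stream for association analysis
#'
#' Group-membership inference ("gambit of the group") expects one row
#' per detection with elapsed time in seconds from the start of the
#' stream, the individual, and its location. Suitable as input for
#' Gaussian-mixture event grouping or time-window association.
#'
#' @param d Detection table.
#' @return A `perch_event_stream` tibble: `time` (seconds since first
#'   read, non-decreasing), `animal_id`, `location`.
#' @export
export_event_stream <- function(d) {
  require_columns(d, c("animal_id", "logger_id", "time"),
    what = "detection table")
  d <- as_tibble(d)
  d <- arrange(d, .data$time, .data$animal_id, .data$logger_id)
  origin <- if (nrow(d) > 0) min(d$time) else NA
  out <- tibble(
    time = if (nrow(d) > 0) secs_between(d$time, origin) else numeric(),
    animal_id = as.character(d$animal_id),
    location = as.character(d$logger_id)
  )
  stamp_class(out, "perch_event_stream")
}
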