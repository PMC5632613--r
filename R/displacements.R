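#' Displacement (supplanting) events at a logger
#'
#' When one bird forces another off a feeder perch, the detection
#' stream shows the displacee's visit ending and the displacer's visit
#' starting within a second or two. For each logger, visits are
#' ordered by `(start, end, animal_id)` (the tie-break makes
#' simultaneous starts deterministic); every pair of successive visits
#' by *different* animals whose gap (next start minus previous end) is
#' at least 0 and strictly less than `bw` seconds yields one event:
#' the arriving animal is the displacer, the departing one the
#' displacee.
#'
#' @param v Visit table from [visits()].
#' @param bw Gap cutoff in seconds (default 2).
#' @return A `perch_displacements` tibble: `logger_id`, `displacee`,
#'   `displacer`, `displacee_end`, `displacer_start`, `gap_seconds`.
#' @export
displacements <- function(v, bw = 2) {
  require_columns(v, c("animal_id", "logger_id", "start", "end"),
    what = "visit table")
  if (bw <= 0) {
    abort("bw must be a positive number of seconds",
      class = "perchflow_spec_error")
  }
  tz <- attr(v, "tz") %||% tz_of(v$start)
  v <- as_tibble(v)
  v <- arrange(v, .data$logger_id, .data$start, .data$end, .data$animal_id)
  v <- group_by(v, .data$logger_id)
  v <- mutate(v,
    prev_animal = lag(.data$animal_id),
    prev_end = lag(.data$end)
  )
  v <- ungroup(v)
  gap <- secs_between(v$start, v$prev_end)
  keep <- !is.na(v$prev_animal) & v$prev_animal != v$animal_id &
    gap >= 0 & gap_within(gap, bw)
  out <- tibble(
    logger_id = v$logger_id[keep],
    displacee = v$prev_animal[keep],
    displacer = v$animal_id[keep],
    displacee_end = v$prev_end[keep],
    displacer_start = v$start[keep],
    gap_seconds = gap[keep]
  )
  if ("animal_n" %in% names(v)) out$animal_n <- v$animal_n[keep]
  out <- arrange(out, .data$displacer_start, .data$logger_id)
  attr(out, "tz") <- tz
  stamp_class(out, "perch_displacements")
}
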