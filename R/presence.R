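#' Presence bouts: runs of regular visits at one logger
#'
#' Presence measures how long an animal kept *returning* to a station,
#' not just the time spent in read range. Per animal, chronologically
#' ordered visits are chained into a bout while the gap from one
#' visit's end to the next visit's start is strictly less than `bw`
#' minutes; a visit at a different logger breaks the chain. A bout
#' runs from its first chained visit's start to its last chained
#' visit's end, and its `length` (minutes) therefore includes the
#' short gaps between the visits it spans.
#'
#' @param v Visit table from [visits()].
#' @param bw Regularity cutoff in minutes (default 15).
#' @return A `perch_presence` tibble: `animal_id`, `date` (local date
#'   of bout start), `logger_id`, `start`, `end`, `length` (minutes),
#'   plus `animal_n`, coordinates and carried metadata when present.
#' @export
presence <- function(v, bw = 15) {
  require_columns(v, c("animal_id", "logger_id", "start", "end"),
    what = "visit table")
  if (bw <= 0) {
    abort("bw must be a positive number of minutes",
      class = "perchflow_spec_error")
  }
  tz <- attr(v, "tz") %||% tz_of(v$start)
  v <- arrange(as_tibble(v), .data$animal_id, .data$start)
  extras <- extra_cols(v, core_visit_cols)

  v <- group_by(v, .data$animal_id)
  v <- mutate(v,
    .gap = secs_between(.data$start, lag(.data$end)),
    .new_bout = is.na(.data$.gap) |
      .data$logger_id != lag(.data$logger_id) |
      !gap_within(.data$.gap, bw * 60),
    .bout = cumsum(.data$.new_bout)
  )
  v <- ungroup(v)

  p <- v |>
    group_by(.data$animal_id, .data$.bout) |>
    summarise(
      logger_id = dplyr::first(.data$logger_id),
      start = min(.data$start),
      end = max(.data$end),
      across(any_of(c("animal_n", "lat", "lon")), dplyr::first),
      across(all_of(extras), dplyr::first),
      .groups = "drop"
    ) |>
    mutate(
      date = lubridate::as_date(.data$start, tz = tz),
      length = secs_between(.data$end, .data$start) / 60
    ) |>
    arrange(.data$animal_id, .data$start) |>
    select(all_of(c("animal_id", "date", "logger_id", "start", "end",
      "length")), any_of(c("animal_n", "lat", "lon")), all_of(extras))
  attr(p, "tz") <- tz
  stamp_class(p, "perch_presence")
}
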