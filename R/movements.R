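#' Movements between loggers
#'
#' Each pair of chronologically consecutive visits by one animal at
#' two *different* loggers is one movement: the animal left the first
#' logger when its visit there ended and arrived at the second when
#' the next visit started. `strength` is the inverse of the travel
#' time in hours (3600 / elapsed seconds): fast transitions weight an
#' edge heavily, an overnight gap barely at all. `move_dir` is the
#' directed `"<left>_<arrived>"` pair; `move_path` the
#' direction-independent pair with the two logger ids sorted
#' ascending, so both directions share one path label.
#'
#' @param v Visit table from [visits()].
#' @param allow_zero Zero travel time (arrival at the same second as
#'   departure) leaves strength undefined; error by default, or drop
#'   such transitions with a warning.
#' @return A `perch_movements` tibble, one row per movement:
#'   `animal_id`, `move_id` (per-animal ordinal from 1), `left_logger`,
#'   `left_time`, `arrived_logger`, `arrived_time`, `move_dir`,
#'   `move_path`, `strength`, endpoint coordinates when present, and
#'   carried metadata. Use [movements_long()] for the two-row
#'   (left/arrived) view.
#' @export
movements <- function(v, allow_zero = FALSE) {
  require_columns(v, c("animal_id", "logger_id", "start", "end"),
    what = "visit table")
  tz <- attr(v, "tz") %||% tz_of(v$start)
  v <- arrange(as_tibble(v), .data$animal_id, .data$start)
  extras <- extra_cols(v, core_visit_cols)
  has_coords <- all(c("lat", "lon") %in% names(v))

  v <- group_by(v, .data$animal_id)
  m <- mutate(v,
    left_logger = lag(.data$logger_id),
    left_time = lag(.data$end),
    left_lat = if (has_coords) lag(.data$lat) else NA_real_,
    left_lon = if (has_coords) lag(.data$lon) else NA_real_
  )
  m <- ungroup(m)
  m <- filter(m, !is.na(.data$left_logger),
    .data$left_logger != .data$logger_id)

  dt <- secs_between(m$start, m$left_time)
  if (any(dt <= 0)) {
    if (!allow_zero || any(dt < 0)) {
      i <- which(dt <= 0)[1]
      abort(
        sprintf(
          "animal %s: arrival at %s (%s) not after departure from %s (%s)",
          m$animal_id[i], m$logger_id[i], format(m$start[i]),
          m$left_logger[i], format(m$left_time[i])
        ),
        class = "perchflow_impossible_error"
      )
    }
    warn(sprintf("dropping %d zero-travel-time movement(s)", sum(dt == 0)))
    m <- m[dt > 0, ]
    dt <- dt[dt > 0]
  }

  out <- tibble(
    animal_id = m$animal_id,
    left_logger = m$left_logger,
    left_time = m$left_time,
    arrived_logger = m$logger_id,
    arrived_time = m$start,
    move_dir = paste(m$left_logger, m$logger_id, sep = "_"),
    move_path = purrr::map2_chr(m$left_logger, m$logger_id,
      ~ paste(sort(c(.x, .y)), collapse = "_")),
    strength = 3600 / dt
  )
  if ("animal_n" %in% names(m)) out$animal_n <- m$animal_n
  if (has_coords) {
    out$left_lat <- m$left_lat
    out$left_lon <- m$left_lon
    out$arrived_lat <- m$lat
    out$arrived_lon <- m$lon
  }
  for (nm in extras) out[[nm]] <- m[[nm]]
  out <- arrange(out, .data$animal_id, .data$left_time)
  out <- out |>
    group_by(.data$animal_id) |>
    mutate(move_id = row_number()) |>
    ungroup() |>
    select(all_of(c("animal_id", "move_id")), dplyr::everything())
  attr(out, "tz") <- tz
  stamp_class(out, "perch_movements")
}

#' Long (two-row) movement view
#'
#' Expands each movement into a departure row and an arrival row
#' (`direction` of `"left"` / `"arrived"`), the layout that exported
#' movement tables use.
#'
#' @param m Movement table from [movements()].
#' @return Tibble with `animal_id`, `date`, `time`, `logger_id`,
#'   `direction`, `move_id`, `move_dir`, `move_path`, `strength` (plus
#'   coordinates / metadata present in `m`).
#' @export
movements_long <- function(m) {
  require_columns(m, c("animal_id", "move_id", "left_logger", "left_time",
    "arrived_logger", "arrived_time", "move_dir", "move_path", "strength"),
  what = "movement table")
  tz <- attr(m, "tz") %||% tz_of(m$left_time)
  extras <- setdiff(names(m), c("animal_id", "move_id", "left_logger",
    "left_time", "arrived_logger", "arrived_time", "left_lat", "left_lon",
    "arrived_lat", "arrived_lon", "move_dir", "move_path", "strength"))
  has_coords <- all(c("left_lat", "left_lon") %in% names(m))

  one <- function(dir) {
    side <- if (dir == "left") "left" else "arrived"
    out <- tibble(
      animal_id = m$animal_id,
      time = m[[paste0(side, "_time")]],
      logger_id = m[[paste0(side, "_logger")]],
      direction = dir,
      move_id = m$move_id,
      move_dir = m$move_dir,
      move_path = m$move_path,
      strength = m$strength
    )
    if (has_coords) {
      out$lat <- m[[paste0(side, "_lat")]]
      out$lon <- m[[paste0(side, "_lon")]]
    }
    for (nm in extras) out[[nm]] <- m[[nm]]
    out
  }
  out <- bind_rows(one("left"), one("arrived"))
  out$date <- lubridate::as_date(out$time, tz = tz)
  out <- arrange(out, .data$animal_id, .data$move_id, .data$time)
  out <- select(out, all_of(c("animal_id", "date", "time", "logger_id",
    "direction", "move_id", "move_dir", "move_path", "strength")),
  dplyr::everything())
  attr(out, "tz") <- tz
  stamp_class(out, "perch_movements_long")
}
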