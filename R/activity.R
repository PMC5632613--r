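#' Score presence bouts onto a binary activity grid
#'
#' Lays a grid of `res`-minute bins, anchored at local midnight, over
#' each animal's observed range (first bout start floored to the grid,
#' last bout end ceiled) and scores each bin active (1) if the
#' half-open bin interval `[bin_start, bin_start + res)` overlaps any
#' presence bout, else inactive (0). Half-open bins mean a bout ending
#' exactly on a bin boundary does not activate the following bin, so
#' no minute is double counted. The grid is trimmed to each animal's
#' observed range so time before deployment or after the last bout is
#' not scored as inactivity.
#'
#' @param p Presence table from [presence()].
#' @param res Bin resolution in minutes; must divide 1440 (default 15).
#' @param by_logger Score per (animal, logger) instead of pooling an
#'   animal's bouts across loggers?
#' @return A `perch_activity` tibble: `animal_id` (`logger_id` when
#'   `by_logger`), `bin_start` (POSIXct on the grid), `active` (0/1).
#' @export
activity_grid <- function(p, res = 15, by_logger = FALSE) {
  require_columns(p, c("animal_id", "logger_id", "start", "end"),
    what = "presence table")
  if (res <= 0 || 1440 %% res != 0) {
    abort("res must be a positive number of minutes dividing 1440",
      class = "perchflow_spec_error")
  }
  tz <- attr(p, "tz") %||% tz_of(p$start)
  p <- as_tibble(p)
  step <- res * 60

  grid_floor <- function(t) {
    midnight <- lubridate::floor_date(t, "day")
    midnight + floor(secs_between(t, midnight) / step) * step
  }

  group_cols <- if (by_logger) c("animal_id", "logger_id") else "animal_id"
  keyframe <- distinct(p[, group_cols, drop = FALSE])
  keyframe <- arrange(keyframe, across(all_of(group_cols)))

  pieces <- vector("list", nrow(keyframe))
  for (i in seq_len(nrow(keyframe))) {
    sel <- rep(TRUE, nrow(p))
    for (k in group_cols) sel <- sel & (p[[k]] == keyframe[[k]][i])
    bouts <- p[sel, , drop = FALSE]
    # last covered bin per bout: with half-open bins the bin holding
    # (end - 1 s) for extended bouts, the bin holding the point for
    # instantaneous ones; the grid runs from the floored first start
    # to the ceiled last end, which is exactly the latest covered bin
    first_bin <- grid_floor(bouts$start)
    last_bin <- dplyr::if_else(bouts$end > bouts$start,
      grid_floor(bouts$end - 1), first_bin)
    last_bin <- pmax(last_bin, first_bin)
    lo <- grid_floor(min(bouts$start))
    hi <- max(max(last_bin), lo)
    bins <- seq(lo, hi, by = step)
    active <- rep(0L, length(bins))
    for (j in seq_len(nrow(bouts))) {
      idx <- which(bins >= first_bin[j] & bins <= last_bin[j])
      active[idx] <- 1L
    }
    piece <- tibble(bin_start = bins, active = active)
    for (k in rev(group_cols)) {
      piece[[k]] <- keyframe[[k]][i]
      piece <- select(piece, all_of(k), dplyr::everything())
    }
    pieces[[i]] <- piece
  }
  out <- bind_rows(pieces)
  if (nrow(keyframe) == 0) {
    out <- tibble(animal_id = character(),
      bin_start = as.POSIXct(character(), tz = tz), active = integer())
    if (by_logger) {
      out$logger_id <- character()
      out <- select(out, all_of(c("animal_id", "logger_id")),
        dplyr::everything())
    }
  }
  attr(out, "tz") <- tz
  attr(out, "res") <- res
  stamp_class(out, "perch_activity")
}

#' Average the activity grid into a daily (24-h) pattern
#'
#' For each animal and time-of-day bin, the proportion of observed
#' days on which that bin was active. Days on which the animal's grid
#' has no cell in a bin (before first or after last bout) do not enter
#' the denominator; `n_days` reports how many days did.
#'
#' @param a Activity grid from [activity_grid()].
#' @return A `perch_daily` tibble: `animal_id`, `time_of_day` (minutes
#'   after local midnight), `p_active` in `[0, 1]`, `n_days`.
#' @export
daily_pattern <- function(a) {
  require_columns(a, c("animal_id", "bin_start", "active"),
    what = "activity grid")
  tz <- attr(a, "tz") %||% tz_of(a$bin_start)
  a <- as_tibble(a)
  a$time_of_day <- secs_after_midnight(a$bin_start) / 60
  a$.day <- lubridate::as_date(a$bin_start, tz = tz)
  out <- a |>
    group_by(.data$animal_id, .data$time_of_day) |>
    summarise(
      p_active = mean(.data$active > 0),
      n_days = n_distinct(.data$.day),
      .groups = "drop"
    ) |>
    arrange(.data$animal_id, .data$time_of_day)
  attr(out, "tz") <- tz
  stamp_class(out, "perch_daily")
}

#' Export per-animal event times as radians for circular analysis
#'
#' Circular kernel density tools for diel activity expect event times
#' as radians on the 24-h clock. Each event's start time maps to
#' `2 * pi * (seconds after local midnight) / 86400`, grouped per
#' animal.
#'
#' @param d A detection table (uses `time`) or visit/presence table
#'   (uses `start`).
#' @return Named list, one numeric vector of radians in `[0, 2 * pi)`
#'   per animal.
#' @export
export_time_vectors <- function(d) {
  require_columns(d, "animal_id", what = "input")
  tcol <- if ("time" %in% names(d)) "time" else if ("start" %in% names(d)) {
    "start"
  } else {
    abort("input needs a 'time' or 'start' column",
      class = "perchflow_input_error")
  }
  rad <- 2 * pi * secs_after_midnight(d[[tcol]]) / 86400
  split(rad, as.character(d$animal_id))
}
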