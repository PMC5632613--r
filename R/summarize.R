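#' Summarize presence for mapping
#'
#' Collapses presence bouts into per-logger amounts for the map
#' renderer. Modes:
#'
#' * `"sum"` - total minutes of presence per logger.
#' * `"sum_indiv"` - the total averaged by the number of individuals
#'   in the source data (`animal_n`, stamped by [visits()]).
#' * `"indiv"` - per (animal, logger) totals, optionally restricted to
#'   the ids in `which`.
#' * `"none"` - pass-through for caller-precomputed summaries (e.g.
#'   grouped workflows); validates the schema (`logger_id`, `amount`)
#'   and returns the input untouched.
#'
#' @param p Presence table from [presence()] (mode `"none"`: any table
#'   with `logger_id` and `amount`).
#' @param mode One of `"sum"`, `"sum_indiv"`, `"indiv"`, `"none"`.
#' @param which Optional animal ids, only with mode `"indiv"`.
#' @param keys Optional grouping columns (e.g. `"experiment"`) kept in
#'   the summary; totals are computed within each key combination.
#' @return A `perch_presence_summary` tibble: key columns, `logger_id`,
#'   `lat`/`lon` when present, `amount` (minutes), and `animal_id` for
#'   mode `"indiv"`.
#' @export
summarize_presence <- function(p, mode = c("sum", "sum_indiv", "indiv",
                                 "none"), which = NULL, keys = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") {
    require_columns(p, c("logger_id", "amount"), what = "summary table")
    return(stamp_class(as_tibble(p), "perch_presence_summary"))
  }
  require_columns(p, c("animal_id", "logger_id", "length"),
    what = "presence table")
  if (!is.null(keys)) require_columns(p, keys, what = "presence table")
  if (!is.null(which) && mode != "indiv") {
    abort("'which' is only meaningful with mode = \"indiv\"",
      class = "perchflow_spec_error")
  }
  if (mode == "sum_indiv") {
    require_columns(p, "animal_n", what = "presence table")
  }
  p <- as_tibble(p)
  p$length <- as.numeric(p$length)
  coord_cols <- intersect(c("lat", "lon"), names(p))

  if (mode == "indiv") {
    if (!is.null(which)) {
      unknown <- setdiff(which, unique(p$animal_id))
      if (length(unknown) > 0) {
        abort(sprintf("unknown animal id(s) in 'which': %s",
          paste(unknown, collapse = ", ")),
        class = "perchflow_input_error")
      }
      p <- filter(p, .data$animal_id %in% which)
    }
    group_cols <- c(keys, "animal_id", "logger_id", coord_cols)
  } else {
    group_cols <- c(keys, "logger_id", coord_cols)
  }

  out <- p |>
    group_by(across(all_of(group_cols))) |>
    summarise(
      amount = if (mode == "sum_indiv") {
        sum(.data$length) / .data$animal_n[1]
      } else {
        sum(.data$length)
      },
      .groups = "drop"
    ) |>
    arrange(across(all_of(group_cols)))
  stamp_class(out, "perch_presence_summary")
}

#' Summarize movements for mapping
#'
#' Collapses movement events into per-path use counts. Modes mirror
#' [summarize_presence()]: `"sum"` counts movements per undirected
#' `move_path`, `"sum_indiv"` divides by `animal_n`, `"indiv"` counts
#' per (animal, path), `"none"` validates and passes a precomputed
#' summary (`move_path`, `path_use`) through. Endpoint coordinates are
#' attached from the events when available (columns `logger_1`,
#' `lat_1`, `lon_1`, `logger_2`, `lat_2`, `lon_2`, with the endpoints
#' in move_path order).
#'
#' @param m Movement table from [movements()].
#' @inheritParams summarize_presence
#' @return A `perch_movement_summary` tibble with `move_path`,
#'   endpoint columns, `path_use`, and `animal_id` for mode `"indiv"`.
#' @export
summarize_movements <- function(m, mode = c("sum", "sum_indiv", "indiv",
                                  "none"), which = NULL, keys = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") {
    require_columns(m, c("move_path", "path_use"), what = "summary table")
    return(stamp_class(as_tibble(m), "perch_movement_summary"))
  }
  require_columns(m, c("animal_id", "move_path"), what = "movement table")
  if (!is.null(keys)) require_columns(m, keys, what = "movement table")
  if (!is.null(which) && mode != "indiv") {
    abort("'which' is only meaningful with mode = \"indiv\"",
      class = "perchflow_spec_error")
  }
  if (mode == "sum_indiv") {
    require_columns(m, "animal_n", what = "movement table")
  }
  m <- as_tibble(m)

  if (mode == "indiv") {
    if (!is.null(which)) {
      unknown <- setdiff(which, unique(m$animal_id))
      if (length(unknown) > 0) {
        abort(sprintf("unknown animal id(s) in 'which': %s",
          paste(unknown, collapse = ", ")),
        class = "perchflow_input_error")
      }
      m <- filter(m, .data$animal_id %in% which)
    }
    group_cols <- c(keys, "animal_id", "move_path")
  } else {
    group_cols <- c(keys, "move_path")
  }

  out <- m |>
    group_by(across(all_of(group_cols))) |>
    summarise(
      path_use = if (mode == "sum_indiv") n() / .data$animal_n[1] else n(),
      .groups = "drop"
    )

  # endpoints from the events themselves (not by splitting move_path,
  # which would misparse logger ids containing "_")
  if (all(c("left_logger", "arrived_logger") %in% names(m))) {
    ends <- m |>
    mutate(
      logger_1 = pmin(.data$left_logger, .data$arrived_logger),
      logger_2 = pmax(.data$left_logger, .data$arrived_logger)
    ) |>
    distinct(.data$move_path, .data$logger_1, .data$logger_2)
    out <- left_join(out, ends, by = "move_path")
    coords <- movement_endpoint_coords(m)
    if (!is.null(coords)) {
      out <- left_join(out,
        setNames(coords, c("logger_1", "lat_1", "lon_1")), by = "logger_1")
      out <- left_join(out,
        setNames(coords, c("logger_2", "lat_2", "lon_2")), by = "logger_2")
    }
  }
  out <- arrange(out, across(all_of(group_cols)))
  stamp_class(out, "perch_movement_summary")
}

movement_endpoint_coords <- function(m) {
  if (!all(c("left_lat", "left_lon", "arrived_lat", "arrived_lon") %in%
    names(m))) {
    return(NULL)
  }
  coords <- bind_rows(
    tibble(logger_id = m$left_logger, lat = m$left_lat, lon = m$left_lon),
    tibble(logger_id = m$arrived_logger, lat = m$arrived_lat,
      lon = m$arrived_lon)
  )
  coords <- distinct(filter(coords, !is.na(.data$lat) & !is.na(.data$lon)))
  if (nrow(coords) == 0) NULL else coords
}
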