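#' Consolidate raw reads into visits
#'
#' A visit is a maximal run of reads by one animal at one logger in
#' which every inter-read gap is strictly less than `bw` seconds. A
#' logger change always ends a visit; a single isolated read yields a
#' visit with `start == end`. Perch-mounted RFID receivers re-read a
#' tag every couple of seconds while the bird sits, so the read train
#' collapses to the span actually spent in range.
#'
#' `animal_n`, the number of distinct animals in the source table, is
#' stamped on every visit; downstream per-individual averaging
#' (`summary = "sum_indiv"`) divides by it.
#'
#' The same animal read at two different loggers less than `bw`
#' seconds apart is physically impossible and indicates tag cloning or
#' clock skew; by default this raises an error naming the animal,
#' loggers and times. With `allow_imp = TRUE` the later read of each
#' impossible pair is dropped with a warning.
#'
#' @param d Detection table from [load_format()] / [load_raw_all()]
#'   (any data frame with `animal_id`, `logger_id`, `time` works).
#' @param bw Gap cutoff in seconds (default 3).
#' @param allow_imp Drop impossible reads instead of erroring?
#' @return A `perch_visits` tibble: `animal_id`, `date`, `start`,
#'   `end`, `logger_id`, `animal_n`, plus `lat`/`lon` and carried
#'   metadata when present.
#' @examples
#' d <- tibble::tibble(
#'   animal_id = "a", logger_id = "L1",
#'   time = as.POSIXct("2015-10-01 17:38:52", tz = "UTC") + c(0, 2, 4, 20)
#' )
#' visits(d, bw = 3)
#' @export
visits <- function(d, bw = 3, allow_imp = FALSE) {
  require_columns(d, c("animal_id", "logger_id", "time"),
    what = "detection table")
  if (bw <= 0) {
    abort("bw must be a positive number of seconds",
      class = "perchflow_spec_error")
  }
  tz <- attr(d, "tz") %||% tz_of(d$time)
  d <- as_tibble(d)
  d$animal_id <- as.character(d$animal_id)
  d$logger_id <- as.character(d$logger_id)
  d <- arrange(d, .data$animal_id, .data$time)
  d <- drop_impossible(d, bw, allow_imp)
  extras <- extra_cols(d, core_read_cols)
  n_animals <- n_distinct(d$animal_id)

  if (nrow(d) == 0) {
    return(empty_visits(extras, d, tz))
  }

  d <- group_by(d, .data$animal_id)
  d <- mutate(d,
    .gap = secs_between(.data$time, lag(.data$time)),
    .new_visit = is.na(.gap) | .data$logger_id != lag(.data$logger_id) |
      !gap_within(.data$.gap, bw),
    .visit = cumsum(.data$.new_visit)
  )
  d <- ungroup(d)

  v <- d |>
    group_by(.data$animal_id, .data$.visit) |>
    summarise(
      logger_id = dplyr::first(.data$logger_id),
      start = min(.data$time),
      end = max(.data$time),
      across(any_of(c("lat", "lon")), dplyr::first),
      across(all_of(extras), dplyr::first),
      .groups = "drop"
    ) |>
    mutate(
      date = lubridate::as_date(.data$start, tz = tz),
      animal_n = n_animals
    ) |>
    arrange(.data$animal_id, .data$start) |>
    select(all_of(c("animal_id", "date", "start", "end", "logger_id",
      "animal_n")), any_of(c("lat", "lon")), all_of(extras))
  attr(v, "tz") <- tz
  stamp_class(v, "perch_visits")
}

empty_visits <- function(extras, d, tz) {
  v <- tibble(
    animal_id = character(), date = as.Date(character()),
    start = as.POSIXct(character(), tz = tz),
    end = as.POSIXct(character(), tz = tz),
    logger_id = character(), animal_n = integer()
  )
  for (nm in intersect(c("lat", "lon"), names(d))) v[[nm]] <- numeric()
  for (nm in extras) v[[nm]] <- d[[nm]][0]
  attr(v, "tz") <- tz
  stamp_class(v, "perch_visits")
}

# Same animal at two loggers within the visit cutoff: error, or under
# allow_imp drop the later read of each offending pair and re-check.
drop_impossible <- function(d, bw, allow_imp) {
  repeat {
    if (nrow(d) < 2) return(d)
    gap <- secs_between(d$time[-1], d$time[-nrow(d)])
    same_animal <- d$animal_id[-1] == d$animal_id[-nrow(d)]
    diff_logger <- d$logger_id[-1] != d$logger_id[-nrow(d)]
    bad <- which(same_animal & diff_logger & gap_within(gap, bw))
    if (length(bad) == 0) return(d)
    i <- bad[1]
    if (!allow_imp) {
      abort(
        sprintf(
          paste0("impossible detections: animal %s read at logger %s ",
            "(%s) and logger %s (%s) within %s s"),
          d$animal_id[i], d$logger_id[i], format(d$time[i]),
          d$logger_id[i + 1], format(d$time[i + 1]), bw
        ),
        class = "perchflow_impossible_error"
      )
    }
    warn(sprintf(
      "dropping impossible read: animal %s at logger %s (%s)",
      d$animal_id[i + 1], d$logger_id[i + 1], format(d$time[i + 1])
    ))
    d <- d[-(i + 1), ]
  }
}
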