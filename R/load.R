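#' Format a pre-labelled detection table
#'
#' Takes a data frame of raw detections with at least `animal_id`,
#' `logger_id` and `time` columns (`lat`/`lon` optional, any further
#' columns are carried through unmodified), parses the time column
#' under a time spec, localizes it to `tz`, derives the local calendar
#' `date`, coerces ids to character and sorts by `(animal_id, time)`.
#'
#' @param d Data frame of detections.
#' @param time_format Time spec string (see [parse_time_spec()]).
#' @param tz IANA timezone name the timestamps are local to.
#' @param dedup Drop exact duplicate rows (same animal, logger and
#'   second)? Defaults to `FALSE`: duplicate reads are consolidated by
#'   [visits()] anyway.
#' @return A `perch_reads` tibble, one row per detection.
#' @examples
#' raw <- tibble::tibble(
#'   animal_id = "041868E9A8", logger_id = "2100",
#'   time = "2015-10-01 17:38:52"
#' )
#' load_format(raw)
#' @export
load_format <- function(d, time_format = "ymd HMS", tz = "UTC",
                        dedup = FALSE) {
  require_columns(d, c("animal_id", "logger_id", "time"),
    what = "detection table")
  d <- as_tibble(d)
  d$animal_id <- as.character(d$animal_id)
  d$logger_id <- as.character(d$logger_id)
  if (inherits(d$time, "POSIXct")) {
    d$time <- lubridate::with_tz(d$time, tz)
  } else {
    raw_time <- as.character(d$time)
    d$time <- parse_timestamps(raw_time, time_format, tz)
    bad <- which(is.na(d$time) & !is.na(raw_time))
    if (length(bad) > 0) {
      abort(
        sprintf(
          "time value '%s' (row %d) does not parse under spec \"%s\"",
          raw_time[bad[1]], bad[1], parse_time_spec(time_format)$order
        ),
        class = "perchflow_input_error"
      )
    }
  }
  if (anyNA(d$time)) {
    abort(sprintf("missing time at row %d", which(is.na(d$time))[1]),
      class = "perchflow_input_error")
  }
  blank <- !nzchar(d$animal_id) | !nzchar(d$logger_id) |
    is.na(d$animal_id) | is.na(d$logger_id)
  if (any(blank)) {
    abort(sprintf("empty animal_id or logger_id at row %d", which(blank)[1]),
      class = "perchflow_input_error")
  }
  if (all(c("lat", "lon") %in% names(d))) {
    d$lat <- as.numeric(d$lat)
    d$lon <- as.numeric(d$lon)
    check_latlon(d$lat, d$lon)
  }
  d$date <- lubridate::as_date(d$time, tz = tz)
  if (dedup) {
    d <- distinct(d, .data$animal_id, .data$logger_id, .data$time,
      .keep_all = TRUE)
  }
  lead_cols <- intersect(
    c("animal_id", "time", "logger_id", "lat", "lon", "date"), names(d)
  )
  d <- select(d, all_of(lead_cols), dplyr::everything())
  d <- arrange(d, .data$animal_id, .data$time)
  attr(d, "tz") <- tz
  stamp_class(d, "perch_reads")
}

split_fields <- function(lines, sep) {
  sep <- match.arg(sep, c("ws", "whitespace", ",", ";", "comma", "semicolon"))
  sep <- switch(sep,
    whitespace = "ws", comma = ",", semicolon = ";", sep)
  if (sep == "ws") {
    strsplit(trimws(lines), "[ \t]+")
  } else {
    lapply(strsplit(lines, sep, fixed = TRUE), trimws)
  }
}

#' Read one raw per-logger detection file
#'
#' Raw station files carry three unlabeled columns - animal id, date,
#' and time-of-day - and identify their logger in one of three
#' dialects selected by `details`:
#'
#' * `details = 1` (default): the logger id is the first line of the
#'   file.
#' * `details = 2`: first line logger id, second line the station
#'   coordinates as `lat, lon`; all records are georeferenced from it.
#' * `details = 0`: the logger id is taken from the file name (the
#'   stem, extension stripped), optionally filtered through
#'   `logger_pattern`, a regular expression whose first match is used.
#'
#' @param path Path to the file.
#' @param details Dialect selector, `0`, `1` or `2`.
#' @param sep Field separator: `"ws"` (any run of blanks/tabs, the
#'   default), `","` or `";"`.
#' @param time_format Time spec for the concatenated date + time
#'   fields; defaults to `"mdy HMS"` (month-first, as typical logger
#'   firmware writes).
#' @param tz Timezone of the timestamps.
#' @param logger_pattern Optional regular expression applied to the
#'   file stem under `details = 0`.
#' @return A `perch_reads` tibble.
#' @export
load_raw_file <- function(path, details = 1, sep = "ws",
                          time_format = "mdy HMS", tz = "UTC",
                          logger_pattern = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path),
      class = "perchflow_input_error")
  }
  if (!details %in% c(0, 1, 2)) {
    abort("details must be 0, 1 or 2", class = "perchflow_spec_error")
  }
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  lat <- lon <- NA_real_
  if (details == 0) {
    stem <- tools::file_path_sans_ext(basename(path))
    if (!is.null(logger_pattern)) {
      m <- regmatches(stem, regexpr(logger_pattern, stem))
      if (length(m) == 0) {
        abort(
          sprintf("logger_pattern '%s' matches nothing in file name '%s'",
            logger_pattern, basename(path)),
          class = "perchflow_input_error"
        )
      }
      logger_id <- m[1]
    } else {
      logger_id <- stem
    }
    body <- lines
  } else {
    logger_id <- trimws(lines[1])
    if (length(lines) < 1 || !nzchar(logger_id)) {
      abort(sprintf("empty logger id header in %s", basename(path)),
        class = "perchflow_input_error")
    }
    if (length(split_fields(logger_id, sep)[[1]]) != 1) {
      abort(
        sprintf(
          "%s: header line '%s' looks like a data line; wrong details value?",
          basename(path), logger_id
        ),
        class = "perchflow_input_error"
      )
    }
    body <- lines[-1]
    if (details == 2) {
      coord_line <- if (length(body) > 0) body[1] else ""
      m <- regexec(
        "^\\s*(-?[0-9]+\\.?[0-9]*)\\s*,\\s*(-?[0-9]+\\.?[0-9]*)\\s*$",
        coord_line
      )
      parts <- regmatches(coord_line, m)[[1]]
      if (length(parts) != 3) {
        abort(
          sprintf("malformed coordinate line in %s: '%s' (expected 'lat, lon')",
            basename(path), coord_line),
          class = "perchflow_input_error"
        )
      }
      lat <- as.numeric(parts[2])
      lon <- as.numeric(parts[3])
      body <- body[-1]
    }
  }
  body_keep <- nzchar(trimws(body))
  body_lineno <- which(body_keep) + (length(lines) - length(body))
  body <- body[body_keep]
  if (length(body) == 0) {
    d <- tibble(animal_id = character(), logger_id = character(),
      time = character())
    return(load_format(d, time_format = time_format, tz = tz))
  }
  fields <- split_fields(body, sep)
  nf <- lengths(fields)
  if (any(nf != 3)) {
    bad <- which(nf != 3)[1]
    abort(
      sprintf("%s line %d: expected 3 columns, found %d",
        basename(path), body_lineno[bad], nf[bad]),
      class = "perchflow_input_error"
    )
  }
  mat <- do.call(rbind, fields)
  d <- tibble(
    animal_id = mat[, 1],
    logger_id = logger_id,
    time = paste(mat[, 2], mat[, 3])
  )
  if (!is.na(lat)) {
    d$lat <- lat
    d$lon <- lon
  }
  load_format(d, time_format = time_format, tz = tz)
}

#' Read and combine every raw file in a directory
#'
#' Applies [load_raw_file()] to each file in `dir` (there may be more
#' than one file per logger) and concatenates the results, re-sorted
#' by `(animal_id, time)`.
#'
#' @inheritParams load_raw_file
#' @param dir Directory of raw files.
#' @param pattern Optional file name filter passed to [list.files()].
#' @return A `perch_reads` tibble.
#' @export
load_raw_all <- function(dir, details = 1, sep = "ws",
                         time_format = "mdy HMS", tz = "UTC",
                         logger_pattern = NULL, pattern = NULL) {
  if (!dir.exists(dir)) {
    abort(sprintf("directory not found: %s", dir),
      class = "perchflow_input_error")
  }
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) {
    abort(sprintf("no data files in %s", dir),
      class = "perchflow_input_error")
  }
  parts <- lapply(files, function(f) {
    tryCatch(
      load_raw_file(f, details = details, sep = sep,
        time_format = time_format, tz = tz,
        logger_pattern = logger_pattern),
      error = function(e) {
        abort(sprintf("while reading %s: %s", basename(f), conditionMessage(e)),
          class = class(e)[1], parent = e)
      }
    )
  })
  d <- bind_rows(parts)
  d <- arrange(d, .data$animal_id, .data$time)
  attr(d, "tz") <- tz
  stamp_class(d, "perch_reads")
}

#' Build a logger index
#'
#' A logger index maps each station id to its coordinates. Input is a
#' data frame (or CSV path) with columns `logger_id`, `lat`, `lon`.
#'
#' @param x Data frame or path to a CSV file.
#' @return A validated `perch_logger_index` tibble.
#' @export
logger_index <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  require_columns(x, c("logger_id", "lat", "lon"), what = "logger index")
  x <- as_tibble(x)
  x$logger_id <- as.character(x$logger_id)
  if (anyDuplicated(x$logger_id) > 0) {
    abort(
      sprintf("duplicate logger_id in index: %s",
        x$logger_id[duplicated(x$logger_id)][1]),
      class = "perchflow_input_error"
    )
  }
  x$lat <- as.numeric(x$lat)
  x$lon <- as.numeric(x$lon)
  check_latlon(x$lat, x$lon)
  stamp_class(select(x, all_of(c("logger_id", "lat", "lon"))),
    "perch_logger_index")
}

#' Attach station coordinates from a logger index
#'
#' Fills `lat`/`lon` on a detection table by `logger_id` lookup.
#' Coordinates already present are kept unless `overwrite = TRUE`;
#' loggers absent from the index keep missing coordinates and are
#' listed in a warning (also available as
#' `attr(result, "unmatched_loggers")`).
#'
#' @param d Detection table (any table with a `logger_id` column).
#' @param idx Logger index ([logger_index()] input forms accepted).
#' @param overwrite Replace existing non-missing coordinates?
#' @return `d` with `lat`/`lon` filled.
#' @export
merge_logger_index <- function(d, idx, overwrite = FALSE) {
  require_columns(d, "logger_id", what = "detection table")
  idx <- logger_index(idx)
  keep_class <- class(d)
  keep_tz <- attr(d, "tz")
  lookup_lat <- setNames(idx$lat, idx$logger_id)
  lookup_lon <- setNames(idx$lon, idx$logger_id)
  if (!"lat" %in% names(d)) d$lat <- NA_real_
  if (!"lon" %in% names(d)) d$lon <- NA_real_
  hit <- d$logger_id %in% idx$logger_id
  fill <- hit & (overwrite | is.na(d$lat) | is.na(d$lon))
  d$lat[fill] <- unname(lookup_lat[d$logger_id[fill]])
  d$lon[fill] <- unname(lookup_lon[d$logger_id[fill]])
  unmatched <- sort(unique(d$logger_id[!hit]))
  if (length(unmatched) > 0) {
    warn(sprintf("loggers not in index: %s",
      paste(unmatched, collapse = ", ")))
  }
  attr(d, "unmatched_loggers") <- unmatched
  attr(d, "tz") <- keep_tz
  class(d) <- keep_class
  d
}

#' Write any perchflow table as CSV
#'
#' Timestamps are written as local ISO 8601 (`YYYY-MM-DD HH:MM:SS`,
#' second precision, no timezone suffix) so that a written table
#' reloads bit-identically under the same `tz`.
#'
#' @param d Tibble to write.
#' @param path Output path.
#' @return `d`, invisibly.
#' @export
write_perch_csv <- function(d, path) {
  out <- as_tibble(d)
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) {
      out[[nm]] <- format(out[[nm]], "%Y-%m-%d %H:%M:%S")
    }
    if (inherits(out[[nm]], "difftime")) {
      out[[nm]] <- as.numeric(out[[nm]])
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(d)
}

#' Reload a CSV written by [write_perch_csv()]
#'
#' @param path CSV path.
#' @param tz Timezone the timestamps are local to.
#' @return Tibble with `time`/`start`/`end`/`bin_start` columns parsed
#'   to POSIXct and `date` to Date.
#' @export
read_perch_csv <- function(path, tz = "UTC") {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()))
  for (nm in intersect(c("time", "start", "end", "bin_start",
    "left_time", "arrived_time", "displacee_end", "displacer_start"),
  names(d))) {
    d[[nm]] <- parse_timestamps(d[[nm]], "ymd HMS", tz)
  }
  if ("date" %in% names(d)) d$date <- as.Date(d$date)
  for (nm in intersect(c("lat", "lon", "length", "strength", "amount",
    "path_use", "gap_seconds", "active", "p_active", "time_of_day",
    "animal_n", "move_id", "n_days", "lat_1", "lon_1", "lat_2", "lon_2"),
  names(d))) {
    d[[nm]] <- as.numeric(d[[nm]])
  }
  attr(d, "tz") <- tz
  d
}
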