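# Shared internal helpers.

# The one gap comparator used by visits(), displacements() and presence():
# two events are merged / paired when the gap between them is strictly
# less than the cutoff. Centralized so the boundary convention cannot
# drift between transformations.
gap_within <- function(gap_seconds, bw_seconds) {
  gap_seconds < bw_seconds
}

secs_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "secs"))
}

tz_of <- function(x, default = "UTC") {
  tz <- attr(x, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) default else tz[1]
}

# Seconds after local midnight of a POSIXct vector, in its own timezone.
secs_after_midnight <- function(time) {
  tz <- tz_of(time)
  secs_between(time, lubridate::floor_date(time, "day"))
}

stamp_class <- function(x, cls) {
  class(x) <- unique(c(cls, "tbl_df", "tbl", "data.frame"))
  x
}

require_columns <- function(d, cols, what = "input") {
  missing <- setdiff(cols, names(d))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "",
        paste(missing, collapse = ", ")
      ),
      class = "perchflow_input_error"
    )
  }
  invisible(d)
}

check_latlon <- function(lat, lon) {
  bad_lat <- !is.na(lat) & (lat < -90 | lat > 90)
  bad_lon <- !is.na(lon) & (lon < -180 | lon > 180)
  if (any(bad_lat)) {
    abort(sprintf("latitude out of [-90, 90]: %s", lat[bad_lat][1]),
      class = "perchflow_input_error")
  }
  if (any(bad_lon)) {
    abort(sprintf("longitude out of [-180, 180]: %s", lon[bad_lon][1]),
      class = "perchflow_input_error")
  }
  invisible(NULL)
}

# Columns that belong to the core schemas; everything else is carried
# metadata (species, sex, experiment, ...).
core_read_cols <- c("animal_id", "logger_id", "time", "date", "lat", "lon")
core_visit_cols <- c(
  "animal_id", "logger_id", "date", "start", "end", "animal_n", "lat", "lon"
)

extra_cols <- function(d, core) setdiff(names(d), core)
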