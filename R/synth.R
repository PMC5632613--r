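#' Configuration for the detection-stream simulator
#'
#' The simulator emulates what a grid of RFID-enabled perches records:
#' an animal settles at a station and is re-read every couple of
#' seconds while perched (a read train = one visit), leaves and
#' returns after a short gap (several visits = one presence bout),
#' then departs for much longer and possibly switches station (a
#' movement), with several individuals interleaved at shared stations
#' and overnight-scale gaps arising naturally from long inter-bout
#' waits.
#'
#' All gaps are drawn in whole seconds and kept strictly separable
#' around the transformation cutoffs (`bw_visits` seconds,
#' `bw_presence` minutes) by guard bands, so ground truth is
#' recoverable exactly: the read interval is below the visit cutoff,
#' within-bout gaps lie strictly between the visit cutoff and the
#' presence cutoff, and between-bout gaps exceed the presence cutoff.
#' Infeasible bands raise an error.
#'
#' @param n_animals Number of tagged individuals.
#' @param stations Data frame `logger_id`, `lat`, `lon`; defaults to a
#'   four-feeder grid a few hundred metres apart.
#' @param start Simulation start (parseable timestamp, local to `tz`).
#' @param span_days Length of the simulated deployment in days.
#' @param read_interval Seconds between reads while perched.
#' @param reads_per_visit Integer range `c(min, max)` of reads per
#'   visit (durations follow as `(n - 1) * read_interval`).
#' @param visits_per_bout Integer range of visits chained per bout.
#' @param within_bout_gap Integer range (seconds) of gaps between
#'   visits inside a bout.
#' @param between_bout_gap Integer range (seconds) of gaps between
#'   bouts.
#' @param switch_prob Probability of moving to a different station
#'   between bouts.
#' @param bw_visits,bw_presence The cutoffs (s, min) the guard bands
#'   protect.
#' @param tz Timezone of the deployment.
#' @param seed Integer seed; required by [simulate_detections()].
#' @return A `perch_sim_config` list.
#' @export
sim_config <- function(n_animals = 5,
                       stations = default_stations(),
                       start = "2016-05-01 06:00:00",
                       span_days = 3,
                       read_interval = 2,
                       reads_per_visit = c(2, 8),
                       visits_per_bout = c(1, 5),
                       within_bout_gap = c(5, 300),
                       between_bout_gap = c(1200, 14400),
                       switch_prob = 0.4,
                       bw_visits = 3,
                       bw_presence = 15,
                       tz = "UTC",
                       seed = NULL) {
  stations <- logger_index(stations)
  if (read_interval >= bw_visits) {
    abort("infeasible guard band: read_interval must be < bw_visits",
      class = "perchflow_spec_error")
  }
  if (within_bout_gap[1] <= bw_visits ||
    within_bout_gap[2] >= bw_presence * 60) {
    abort(paste0("infeasible guard band: within_bout_gap must lie ",
      "strictly between bw_visits and bw_presence"),
    class = "perchflow_spec_error")
  }
  if (between_bout_gap[1] <= bw_presence * 60) {
    abort("infeasible guard band: between_bout_gap must exceed bw_presence",
      class = "perchflow_spec_error")
  }
  if (n_animals < 0 || span_days <= 0 || switch_prob < 0 ||
    switch_prob > 1) {
    abort("invalid simulator configuration",
      class = "perchflow_spec_error")
  }
  structure(
    list(
      n_animals = n_animals, stations = stations, start = start,
      span_days = span_days, read_interval = read_interval,
      reads_per_visit = reads_per_visit,
      visits_per_bout = visits_per_bout,
      within_bout_gap = within_bout_gap,
      between_bout_gap = between_bout_gap,
      switch_prob = switch_prob, bw_visits = bw_visits,
      bw_presence = bw_presence, tz = tz, seed = seed
    ),
    class = "perch_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_stations <- function() {
  tibble(
    logger_id = c("2100", "2200", "2400", "2700"),
    lat = c(50.66896, 50.66715, 50.66805, 50.66909),
    lon = c(-120.3624, -120.3610, -120.3650, -120.3632)
  )
}

sample_int <- function(rng, n = 1) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n,
    replace = TRUE)
}

#' Simulate a detection stream with known ground truth
#'
#' Generates interleaved multi-animal read trains under the model
#' described in [sim_config()] and returns both the detections and the
#' ground truth they encode. Because gaps are guard-banded around the
#' cutoffs, running [visits()], [presence()] and [movements()] at
#' those cutoffs recovers the truth exactly; recovery tests exploit
#' this.
#'
#' @param cfg A [sim_config()]; `cfg$seed` must be set.
#' @return List with `detections` (a `perch_reads` tibble) and `truth`
#'   (list of tibbles `visits`, `bouts`, `movements`).
#' @export
simulate_detections <- function(cfg) {
  if (!inherits(cfg, "perch_sim_config")) cfg <- do.call(sim_config, cfg)
  if (is.null(cfg$seed)) {
    abort("cfg$seed must be set for reproducible simulation",
      class = "perchflow_spec_error")
  }
  set.seed(cfg$seed)
  t0 <- parse_timestamps(cfg$start, "ymd HMS", cfg$tz)
  t_end <- t0 + cfg$span_days * 86400
  stations <- cfg$stations

  reads <- list()
  tvisits <- list()
  tbouts <- list()

  for (a in seq_len(cfg$n_animals)) {
    animal <- sprintf("ANIM%02d", a)
    station_i <- sample.int(nrow(stations), 1)
    t <- t0 + sample_int(c(0, 3600))
    while (t < t_end) {
      n_visits <- sample_int(cfg$visits_per_bout)
      bout_start <- t
      bout_station <- stations$logger_id[station_i]
      for (vi in seq_len(n_visits)) {
        n_reads <- sample_int(cfg$reads_per_visit)
        times <- t + (seq_len(n_reads) - 1) * cfg$read_interval
        times <- times[times < t_end]
        if (length(times) == 0) break
        reads[[length(reads) + 1]] <- tibble(
          animal_id = animal,
          logger_id = bout_station,
          time = times,
          lat = stations$lat[station_i],
          lon = stations$lon[station_i]
        )
        tvisits[[length(tvisits) + 1]] <- tibble(
          animal_id = animal, logger_id = bout_station,
          start = times[1], end = times[length(times)]
        )
        t <- times[length(times)]
        if (vi < n_visits) t <- t + sample_int(cfg$within_bout_gap)
        if (t >= t_end) break
      }
      last <- if (length(tvisits) > 0) tvisits[[length(tvisits)]] else NULL
      if (!is.null(last) && last$animal_id == animal &&
        last$start >= bout_start) {
        bout_rows <- which(vapply(tvisits, function(x) {
          x$animal_id == animal && x$start >= bout_start
        }, logical(1)))
        tbouts[[length(tbouts) + 1]] <- tibble(
          animal_id = animal, logger_id = bout_station,
          start = bout_start,
          end = tvisits[[max(bout_rows)]]$end
        )
      }
      t <- t + sample_int(cfg$between_bout_gap)
      if (runif(1) < cfg$switch_prob && nrow(stations) > 1) {
        station_i <- sample(setdiff(seq_len(nrow(stations)), station_i), 1)
      }
    }
  }

  if (length(reads) == 0) {
    d <- tibble(animal_id = character(), logger_id = character(),
      time = as.POSIXct(character(), tz = cfg$tz),
      lat = numeric(), lon = numeric())
    d <- load_format(d, tz = cfg$tz)
    truth <- list(
      visits = tibble(animal_id = character(), logger_id = character(),
        start = d$time, end = d$time),
      bouts = tibble(animal_id = character(), logger_id = character(),
        start = d$time, end = d$time),
      movements = tibble(animal_id = character(),
        left_logger = character(), arrived_logger = character(),
        left_time = d$time, arrived_time = d$time)
    )
    return(list(detections = d, truth = truth))
  }

  d <- bind_rows(reads)
  d <- load_format(d, tz = cfg$tz)

  tv <- arrange(bind_rows(tvisits), .data$animal_id, .data$start)
  tb <- arrange(bind_rows(tbouts), .data$animal_id, .data$start)
  tm <- tv |>
    group_by(.data$animal_id) |>
    mutate(
      left_logger = lag(.data$logger_id),
      left_time = lag(.data$end)
    ) |>
    ungroup() |>
    filter(!is.na(.data$left_logger),
      .data$left_logger != .data$logger_id) |>
    select(all_of(c("animal_id", "left_logger")),
      arrived_logger = "logger_id", "left_time",
      arrived_time = "start")

  list(detections = d,
    truth = list(visits = tv, bouts = tb, movements = tm))
}

#' Write a detection table back out as raw per-logger files
#'
#' One file per logger (named `<logger_id>.txt`, so the file stem
#' doubles as the `details = 0` logger id), three unlabeled columns
#' (animal id, date, time-of-day in `mdy HMS` order) in the chosen
#' dialect: `details = 1` prepends the logger-id header line,
#' `details = 2` also a `lat, lon` coordinate line, `details = 0`
#' writes data lines only. [load_raw_all()] on the directory with the
#' same options round-trips to the input table (coordinates only under
#' `details = 2`).
#'
#' @param d Detection table.
#' @param dir Output directory (created if needed).
#' @param details Dialect, `0`, `1` or `2`.
#' @param sep `"ws"`, `","` or `";"`.
#' @return Character vector of file paths, invisibly.
#' @export
emit_raw_files <- function(d, dir, details = 1, sep = "ws") {
  require_columns(d, c("animal_id", "logger_id", "time"),
    what = "detection table")
  if (!details %in% c(0, 1, 2)) {
    abort("details must be 0, 1 or 2", class = "perchflow_spec_error")
  }
  if (details == 2) {
    require_columns(d, c("lat", "lon"), what = "detection table")
    if (anyNA(d$lat) || anyNA(d$lon)) {
      abort("details = 2 needs coordinates for every logger",
        class = "perchflow_input_error")
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sep_chr <- switch(match.arg(sep, c("ws", "whitespace", ",", ";",
    "comma", "semicolon")),
  ws = " ", whitespace = " ", comma = ",", semicolon = ";",
  `,` = ",", `;` = ";")
  d <- as_tibble(d)
  paths <- character()
  for (lg in sort(unique(d$logger_id))) {
    rows <- d[d$logger_id == lg, , drop = FALSE]
    rows <- arrange(rows, .data$time)
    body <- paste(
      rows$animal_id,
      format(rows$time, "%m/%d/%Y"),
      format(rows$time, "%H:%M:%S"),
      sep = sep_chr
    )
    header <- character()
    if (details >= 1) header <- lg
    if (details == 2) {
      header <- c(header, sprintf("%.5f, %.5f", rows$lat[1], rows$lon[1]))
    }
    path <- file.path(dir, paste0(lg, ".txt"))
    writeLines(c(header, body), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
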