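# Fixtures built in code: the worked example of one female house finch
# detected at three campus feeders, used throughout the docs.

ts <- function(x, tz = "UTC") as.POSIXct(x, tz = tz)

# Ten raw reads: a read train and two stray reads at feeder 2100, then
# the (truncated) start of a train at feeder 2700.
finch_reads <- function() {
  tibble::tibble(
    animal_id = "041868E9A8",
    time = c(
      "2015-10-01 17:38:52", "2015-10-01 17:38:54", "2015-10-01 17:38:56",
      "2015-10-01 17:38:58", "2015-10-01 17:39:00", "2015-10-01 17:39:12",
      "2015-10-01 17:40:53", "2015-10-01 17:45:00", "2015-10-01 17:45:02",
      "2015-10-01 17:45:04"
    ),
    logger_id = c(rep("2100", 7), rep("2700", 3)),
    species = "House Finch",
    sex = "F",
    lon = c(rep(-120.3624, 7), rep(-120.3632, 3)),
    lat = c(rep(50.66896, 7), rep(50.66909, 3))
  )
}

# The full visit history of that finch at feeders 2100 and 2700, plus
# its later detour through feeder 2200 (single-visit boundaries).
finch_visits <- function(tz = "UTC") {
  v <- tibble::tibble(
    animal_id = "041868E9A8",
    logger_id = c(rep("2100", 3), rep("2700", 7), "2200", "2200", "2700"),
    start = ts(c(
      "2015-10-01 17:38:52", "2015-10-01 17:39:12", "2015-10-01 17:40:53",
      "2015-10-01 17:45:00", "2015-10-01 17:46:31", "2015-10-01 17:51:03",
      "2015-10-01 17:51:42", "2015-10-01 17:52:51", "2015-10-01 17:53:41",
      "2015-10-01 17:56:42", "2015-10-02 10:57:00", "2015-10-06 14:24:50",
      "2015-10-06 16:05:40"
    ), tz),
    end = ts(c(
      "2015-10-01 17:39:00", "2015-10-01 17:39:12", "2015-10-01 17:40:53",
      "2015-10-01 17:45:56", "2015-10-01 17:46:31", "2015-10-01 17:51:16",
      "2015-10-01 17:51:58", "2015-10-01 17:53:07", "2015-10-01 17:54:57",
      "2015-10-01 17:56:42", "2015-10-02 10:57:00", "2015-10-06 14:24:50",
      "2015-10-06 16:05:40"
    ), tz),
    animal_n = 1L
  )
  v$date <- as.Date(v$start)
  attr(v, "tz") <- tz
  v
}

# Random detection tables for property tests. Logger switches only
# happen after a gap of at least `switch_guard` seconds, so no
# impossible pattern arises for any visit cutoff below the guard.
random_reads <- function(seed, n_max = 200, switch_guard = 10) {
  set.seed(seed)
  n_animals <- sample(1:5, 1)
  loggers <- sprintf("L%d", 1:sample(1:4, 1))
  origin <- ts("2016-06-01 06:00:00")
  rows <- list()
  for (a in seq_len(n_animals)) {
    n <- sample(2:max(2, n_max %/% n_animals), 1)
    gaps <- sample(c(1, 1, 2, 2, 3, 5, 12, 30, 120, 400, 1000, 2000),
      n - 1, replace = TRUE)
    t <- origin + cumsum(c(sample(0:3600, 1), gaps))
    lg <- character(n)
    lg[1] <- sample(loggers, 1)
    for (i in 2:n) {
      lg[i] <- if (gaps[i - 1] >= switch_guard && runif(1) < 0.3) {
        sample(loggers, 1)
      } else {
        lg[i - 1]
      }
    }
    rows[[a]] <- tibble::tibble(
      animal_id = sprintf("A%02d", a), logger_id = lg, time = t
    )
  }
  dplyr::bind_rows(rows)
}

# Small recovery-oriented simulator configuration: short deployment so
# many seeds can be run quickly.
small_sim_config <- function(seed, n_animals = 3) {
  sim_config(
    n_animals = n_animals,
    span_days = 1,
    between_bout_gap = c(1200, 7200),
    seed = seed
  )
}
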