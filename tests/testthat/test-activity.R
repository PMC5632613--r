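bout <- function(start, end, animal = "a", logger = "L") {
  tibble::tibble(
    animal_id = animal, logger_id = logger,
    start = ts(start), end = ts(end),
    length = secs(ts(end), ts(start)) / 60
  )
}

secs_between_midnight_ok <- function(bin_start, res) {
  mins <- as.numeric(difftime(bin_start,
    as.POSIXct(format(bin_start, "%Y-%m-%d"), tz = "UTC"),
    units = "mins"))
  mins %% res == 0
}


test_that("bins activate by half-open overlap", {
  p <- bout("2016-01-01 10:00:00", "2016-01-01 10:20:00")
  a <- activity_grid(p, res = 15)
  expect_equal(
    format(a$bin_start[a$active == 1], "%H:%M"),
    c("10:00", "10:15")
  )
  # neighbours outside the observed range are never scored active
  expect_false(any(format(a$bin_start, "%H:%M") %in% c("09:45", "10:30") &
    a$active == 1))
  # a bout filling exactly one bin activates only that bin
  p1 <- bout("2016-01-01 10:00:00", "2016-01-01 10:15:00")
  a1 <- activity_grid(p1, res = 15)
  expect_equal(format(a1$bin_start[a1$active == 1], "%H:%M"), "10:00")
})

test_that("oracle: per-bin interval overlap matches the grid", {
  p <- dplyr::bind_rows(
    bout("2016-01-01 08:07:00", "2016-01-01 08:23:00"),
    bout("2016-01-01 09:00:00", "2016-01-01 09:00:00"),
    bout("2016-01-01 11:59:00", "2016-01-01 12:31:00")
  )
  res <- 15
  a <- activity_grid(p, res = res)
  overlap <- function(bin0) {
    any(
      (p$end > bin0 & p$start < bin0 + res * 60) |
        (p$start == p$end & p$start >= bin0 & p$start < bin0 + res * 60)
    )
  }
  want <- vapply(a$bin_start, overlap, logical(1))
  expect_equal(a$active == 1, want)
  # monotone coverage: finer grids never lose a covered bout
  for (r in c(1, 5, 15, 30)) {
    ar <- activity_grid(p, res = r)
    expect_gte(sum(ar$active), nrow(p) - 1)  # two bouts may share a bin
  }
})

test_that("grid bookkeeping: bounds, resolution, empty input", {
  p <- bout("2016-01-01 10:07:00", "2016-01-01 10:20:00")
  a <- activity_grid(p, res = 15)
  expect_equal(format(a$bin_start[1], "%H:%M"), "10:00")
  expect_equal(format(a$bin_start[nrow(a)], "%H:%M"), "10:15")
  expect_true(all(secs_between_midnight_ok(a$bin_start, 15)))
  expect_error(activity_grid(p, res = 13), "1440",
    class = "perchflow_spec_error")
  expect_equal(nrow(activity_grid(p[0, ], res = 15)), 0)
})

test_that("per-logger scoring separates stations", {
  p <- dplyr::bind_rows(
    bout("2016-01-01 10:00:00", "2016-01-01 10:10:00", logger = "L1"),
    bout("2016-01-01 12:00:00", "2016-01-01 12:10:00", logger = "L2")
  )
  pooled <- activity_grid(p, res = 15)
  split <- activity_grid(p, res = 15, by_logger = TRUE)
  expect_false("logger_id" %in% names(pooled))
  expect_true("logger_id" %in% names(split))
  expect_equal(sort(unique(split$logger_id)), c("L1", "L2"))
})

test_that("daily pattern averages activity across observed days", {
  p <- dplyr::bind_rows(
    bout("2016-01-01 10:00:00", "2016-01-01 10:20:00"),
    bout("2016-01-02 10:00:00", "2016-01-02 10:10:00"),
    bout("2016-01-02 11:00:00", "2016-01-02 11:10:00")
  )
  da <- daily_pattern(activity_grid(p, res = 15))
  b1000 <- da[da$time_of_day == 600, ]
  expect_equal(b1000$p_active, 1)
  expect_equal(b1000$n_days, 2)
  # 10:15 active on day 1 only, observed both days
  b1015 <- da[da$time_of_day == 615, ]
  expect_equal(b1015$p_active, 0.5)
  expect_equal(b1015$n_days, 2)
  expect_true(all(da$p_active >= 0 & da$p_active <= 1))
})

test_that("degenerate daily patterns behave", {
  one_day <- daily_pattern(activity_grid(
    bout("2016-01-01 10:00:00", "2016-01-01 10:20:00"), res = 15))
  expect_true(all(one_day$p_active %in% c(0, 1)))
  # all-inactive grid (constructed directly) is identically zero
  g <- tibble::tibble(
    animal_id = "a",
    bin_start = ts("2016-01-01 10:00:00") + c(0, 900),
    active = 0L
  )
  expect_true(all(daily_pattern(g)$p_active == 0))
  # duplicating every day's cells leaves proportions unchanged
  p <- dplyr::bind_rows(
    bout("2016-01-01 10:00:00", "2016-01-01 10:20:00"),
    bout("2016-01-02 11:00:00", "2016-01-02 11:10:00")
  )
  a <- activity_grid(p, res = 15)
  shifted <- dplyr::mutate(a, bin_start = bin_start + 2 * 86400)
  doubled <- daily_pattern(dplyr::bind_rows(a, shifted))
  base <- daily_pattern(a)
  expect_equal(doubled$p_active, base$p_active)
  expect_equal(doubled$n_days, base$n_days * 2)
})

test_that("time vectors map the clock onto the circle", {
  d <- tibble::tibble(
    animal_id = c("a", "a", "b"),
    logger_id = "L",
    time = ts(c("2016-01-01 12:00:00", "2016-01-01 00:00:00",
      "2015-10-01 17:38:52"))
  )
  tv <- export_time_vectors(d)
  expect_named(tv, c("a", "b"))
  expect_equal(tv$a, c(pi, 0))
  expect_equal(tv$b, 2 * pi * 63532 / 86400, tolerance = 1e-9)
  # visit tables use the start column
  v <- finch_visits()
  tv2 <- export_time_vectors(v)
  expect_equal(length(tv2[["041868E9A8"]]), nrow(v))
  expect_true(all(tv2[["041868E9A8"]] >= 0 & tv2[["041868E9A8"]] < 2 * pi))
})
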