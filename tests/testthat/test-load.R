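test_that("load_format parses, sorts, derives dates and keeps metadata", {
  d <- load_format(finch_reads())
  expect_s3_class(d, "perch_reads")
  expect_equal(nrow(d), 10)
  expect_equal(dplyr::n_distinct(d$animal_id), 1)
  expect_equal(sort(unique(d$logger_id)), c("2100", "2700"))
  expect_true(all(d$date == as.Date("2015-10-01")))
  expect_true(all(d$species == "House Finch"))
  expect_false(is.unsorted(d$time))
})

test_that("load_format errors name missing columns and bad times", {
  expect_error(load_format(data.frame(animal_id = "a", time = "x")),
    "logger_id", class = "perchflow_input_error")
  bad <- finch_reads()
  bad$time[3] <- "2015-13-01 00:00:00"
  err <- tryCatch(load_format(bad), error = identity)
  expect_s3_class(err, "perchflow_input_error")
  expect_match(conditionMessage(err), "2015-13-01")
  expect_match(conditionMessage(err), "row 3")
})

test_that("empty input with a valid header loads without error", {
  d <- load_format(finch_reads()[0, ])
  expect_equal(nrow(d), 0)
  expect_true(all(c("animal_id", "logger_id", "time", "date") %in% names(d)))
})

test_that("read conservation and duplicate handling", {
  doubled <- dplyr::bind_rows(finch_reads(), finch_reads()[1, ])
  expect_equal(nrow(load_format(doubled)), 11)
  expect_equal(nrow(load_format(doubled, dedup = TRUE)), 10)
})

test_that("CSV round trip preserves records to the second", {
  d <- load_format(finch_reads())
  path <- withr::local_tempfile(fileext = ".csv")
  write_perch_csv(d, path)
  d2 <- read_perch_csv(path)
  expect_equal(as.numeric(d2$time), as.numeric(d$time))
  expect_equal(d2$animal_id, d$animal_id)
  expect_equal(d2$logger_id, d$logger_id)
  expect_equal(d2$lat, d$lat)
})

test_that("raw-file dialects 0, 1 and 2 load to identical tables", {
  d <- load_format(finch_reads())
  tbl_core <- function(x) {
    y <- as.data.frame(x[, c("animal_id", "logger_id")])
    y$time <- as.numeric(x$time)
    y
  }
  loaded <- list()
  for (details in 0:2) {
    dir <- withr::local_tempdir()
    emit_raw_files(d, dir, details = details)
    loaded[[details + 1]] <- load_raw_all(dir, details = details)
  }
  expect_equal(tbl_core(loaded[[1]]), tbl_core(loaded[[2]]))
  expect_equal(tbl_core(loaded[[2]]), tbl_core(loaded[[3]]))
  # only the details = 2 dialect carries coordinates
  expect_false("lat" %in% names(loaded[[2]]))
  expect_equal(sort(unique(loaded[[3]]$lat)), c(50.66896, 50.66909))
  expect_equal(sort(unique(loaded[[3]]$lon)), c(-120.3632, -120.3624))
})

test_that("single raw file parses the documented example line", {
  dir <- withr::local_tempdir()
  writeLines("041868E9A8 10/01/2015 17:38:52", file.path(dir, "2100.txt"))
  d <- load_raw_file(file.path(dir, "2100.txt"), details = 0)
  expect_equal(d$animal_id, "041868E9A8")
  expect_equal(d$logger_id, "2100")
  expect_equal(as.numeric(d$time), as.numeric(ts("2015-10-01 17:38:52")))
})

test_that("details = 2 extracts the coordinate header", {
  dir <- withr::local_tempdir()
  writeLines(
    c("2700", "50.66909, -120.3632",
      "041868E9A8 10/01/2015 17:45:00",
      "041868E9A8 10/01/2015 17:45:02"),
    file.path(dir, "f.txt")
  )
  d <- load_raw_file(file.path(dir, "f.txt"), details = 2)
  expect_equal(unique(d$lat), 50.66909)
  expect_equal(unique(d$lon), -120.3632)
  expect_equal(unique(d$logger_id), "2700")
})

test_that("raw-file error contracts", {
  dir <- withr::local_tempdir()
  # blank header line under details = 1
  writeLines(c("", "A 10/01/2015 17:38:52"), file.path(dir, "x.txt"))
  expect_error(load_raw_file(file.path(dir, "x.txt"), details = 1),
    "empty logger id", class = "perchflow_input_error")
  # malformed coordinate line under details = 2
  writeLines(c("2700", "not coordinates", "A 10/01/2015 17:38:52"),
    file.path(dir, "y.txt"))
  expect_error(load_raw_file(file.path(dir, "y.txt"), details = 2),
    "not coordinates", class = "perchflow_input_error")
  # wrong column count reports the line number
  writeLines(c("2100", "A 10/01/2015"), file.path(dir, "z.txt"))
  expect_error(load_raw_file(file.path(dir, "z.txt"), details = 1),
    "line 2", class = "perchflow_input_error")
  # logger_pattern that matches nothing names the file
  writeLines("A 10/01/2015 17:38:52", file.path(dir, "stationX.txt"))
  expect_error(
    load_raw_file(file.path(dir, "stationX.txt"), details = 0,
      logger_pattern = "[0-9]+"),
    "stationX", class = "perchflow_input_error"
  )
})

test_that("load_raw_all combines multiple files per logger", {
  d <- load_format(finch_reads())
  dir <- withr::local_tempdir()
  d1 <- d[d$logger_id == "2100", ][1:3, ]
  d2 <- d[d$logger_id == "2100", ][4:7, ]
  emit_raw_files(d1, dir, details = 1)
  file.rename(file.path(dir, "2100.txt"), file.path(dir, "2100_a.txt"))
  emit_raw_files(d2, dir, details = 1)
  all <- load_raw_all(dir, details = 1)
  expect_equal(nrow(all), 7)
  expect_equal(unique(all$logger_id), "2100")
  expect_false(is.unsorted(all$time))
  # empty directory errors
  expect_error(load_raw_all(withr::local_tempdir()), "no data files",
    class = "perchflow_input_error")
  # mixed dialects under details = 1 fail on the nonconforming file
  emit_raw_files(d[d$logger_id == "2700", ], dir, details = 0)
  file.rename(file.path(dir, "2700.txt"), file.path(dir, "2700_raw.txt"))
  expect_error(load_raw_all(dir, details = 1), "2700_raw")
})

test_that("comma and semicolon separators load identically", {
  d <- load_format(finch_reads())
  for (sep in c(",", ";")) {
    dir <- withr::local_tempdir()
    emit_raw_files(d, dir, details = 1, sep = sep)
    got <- load_raw_all(dir, details = 1, sep = sep)
    expect_equal(as.numeric(got$time), as.numeric(d$time))
    expect_equal(got$animal_id, d$animal_id)
  }
})

test_that("logger index merge fills coordinates and reports misses", {
  d <- load_format(finch_reads()[, c("animal_id", "time", "logger_id")])
  idx <- logger_index(tibble::tibble(
    logger_id = c("2100", "2700"),
    lat = c(50.66896, 50.66909),
    lon = c(-120.3624, -120.3632)
  ))
  merged <- merge_logger_index(d, idx)
  expect_false(anyNA(merged$lat))
  expect_equal(merged$lat[merged$logger_id == "2700"][1], 50.66909)
  expect_length(attr(merged, "unmatched_loggers"), 0)

  empty_idx <- logger_index(tibble::tibble(
    logger_id = character(), lat = numeric(), lon = numeric()
  ))
  expect_warning(m2 <- merge_logger_index(d, empty_idx), "2100")
  expect_true(all(is.na(m2$lat)))
  expect_equal(attr(m2, "unmatched_loggers"), c("2100", "2700"))

  expect_error(
    logger_index(tibble::tibble(logger_id = c("a", "a"), lat = 1, lon = 1)),
    "duplicate", class = "perchflow_input_error"
  )
})

test_that("existing coordinates are only overwritten under the flag", {
  d <- load_format(finch_reads())
  idx <- logger_index(tibble::tibble(
    logger_id = c("2100", "2700"), lat = c(1, 2), lon = c(3, 4)
  ))
  kept <- merge_logger_index(d, idx)
  expect_equal(unique(kept$lat[kept$logger_id == "2100"]), 50.66896)
  forced <- merge_logger_index(d, idx, overwrite = TRUE)
  expect_equal(unique(forced$lat[forced$logger_id == "2100"]), 1)
})
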