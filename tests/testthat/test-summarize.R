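test_that("presence summary modes reproduce the worked example amounts", {
  p <- presence(finch_visits(), bw = 15)
  s <- summarize_presence(p, "sum")
  expect_equal(s$amount[s$logger_id == "2100"], 2.016667,
    tolerance = 1e-6)
  # 11.7 min on Oct 1 plus an instantaneous later bout
  expect_equal(s$amount[s$logger_id == "2700"], 11.7, tolerance = 1e-6)
  # single animal: sum_indiv == sum
  p$animal_n <- 1L
  si <- summarize_presence(p, "sum_indiv")
  expect_equal(si$amount, s$amount)
})

test_that("sum_indiv divides by animal_n exactly", {
  p <- tibble::tibble(
    animal_id = c("a", "b"), logger_id = "L",
    start = ts("2016-01-01 10:00:00") + c(0, 5000),
    end = ts("2016-01-01 10:10:00") + c(0, 5000),
    length = 10, animal_n = 2L
  )
  s <- summarize_presence(p, "sum")
  si <- summarize_presence(p, "sum_indiv")
  expect_equal(si$amount * 2, s$amount)
  expect_equal(si$amount, 10)
  # identity holds on random data too
  v <- visits(random_reads(11), bw = 3)
  pr <- presence(v, bw = 15)
  s2 <- summarize_presence(pr, "sum")
  si2 <- summarize_presence(pr, "sum_indiv")
  expect_equal(si2$amount * pr$animal_n[1], s2$amount)
})

test_that("indiv rows add up to the pooled sum and which filters", {
  v <- visits(random_reads(19), bw = 3)
  pr <- presence(v, bw = 15)
  s <- summarize_presence(pr, "sum")
  ind <- summarize_presence(pr, "indiv")
  per_logger <- tapply(ind$amount, ind$logger_id, sum)
  expect_equal(as.vector(per_logger[s$logger_id]), s$amount)
  one <- unique(pr$animal_id)[1]
  w <- summarize_presence(pr, "indiv", which = one)
  expect_true(all(w$animal_id == one))
  expect_error(summarize_presence(pr, "indiv", which = "NOBODY"),
    "NOBODY", class = "perchflow_input_error")
  expect_error(summarize_presence(pr, "sum", which = one),
    class = "perchflow_spec_error")
})

test_that("mode none validates and passes through untouched", {
  pre <- tibble::tibble(logger_id = "L", lat = 1, lon = 2, amount = 5)
  out <- summarize_presence(pre, "none")
  expect_equal(as.data.frame(out), as.data.frame(pre))
  expect_error(summarize_presence(tibble::tibble(logger_id = "L"), "none"),
    "amount", class = "perchflow_input_error")
})

test_that("movement summaries count path use with endpoints", {
  m <- movements(finch_visits())
  s <- summarize_movements(m, "sum")
  expect_equal(nrow(s), 2)
  expect_equal(s$path_use[s$move_path == "2100_2700"], 1)
  expect_equal(s$path_use[s$move_path == "2200_2700"], 2)
  expect_equal(s$logger_1[s$move_path == "2200_2700"], "2200")
  expect_equal(s$logger_2[s$move_path == "2200_2700"], "2700")
  expect_equal(nrow(summarize_movements(m[0, ], "sum")), 0)
})

test_that("movement sum_indiv scales by animal_n", {
  m <- movements(finch_visits())
  m$animal_n <- 1L
  base <- summarize_movements(m, "sum_indiv")
  doubled <- dplyr::mutate(dplyr::bind_rows(m, m), animal_n = 2L)
  halved <- summarize_movements(doubled, "sum_indiv")
  expect_equal(halved$path_use, base$path_use)
  s <- summarize_movements(doubled, "sum")
  expect_equal(halved$path_use * 2, s$path_use)
})

test_that("interaction exports tally winners over losers", {
  d <- tibble::tibble(
    logger_id = "L",
    displacee = c("A", "A", "B"),
    displacer = c("B", "B", "A"),
    displacee_end = ts("2016-01-01 10:00:00") + c(0, 100, 200),
    displacer_start = ts("2016-01-01 10:00:01") + c(0, 100, 200),
    gap_seconds = 1
  )
  ex <- export_interactions(d)
  expect_equal(unname(ex$matrix), matrix(c(0, 2, 1, 0), 2))
  expect_equal(rownames(ex$matrix), c("A", "B"))
  expect_equal(colnames(ex$matrix), c("A", "B"))
  expect_equal(sum(ex$matrix), nrow(ex$sequence))
  expect_true(all(diag(ex$matrix) == 0))
  expect_false(is.unsorted(ex$sequence$time))
  # tidy() long view drops the diagonal
  td <- tidy(ex)
  expect_equal(sum(td$n), 3)
  expect_equal(td$n[td$winner == "B" & td$loser == "A"], 2)
  # degenerate inputs
  ex0 <- export_interactions(d[0, ])
  expect_equal(nrow(ex0$sequence), 0)
  expect_equal(sum(ex0$matrix), 0)
  ex1 <- export_interactions(d[1, ])
  expect_equal(sum(ex1$matrix), 1)
})

test_that("event streams are elapsed-seconds detection lists", {
  d <- load_format(finch_reads())
  es <- export_event_stream(d)
  expect_equal(nrow(es), 10)
  expect_equal(es$time[1], 0)
  expect_equal(es$time[nrow(es)], 372)
  expect_false(is.unsorted(es$time))
  expect_equal(names(es), c("time", "animal_id", "location"))
  # unsorted input still gives a monotonic stream
  es2 <- export_event_stream(d[sample(nrow(d)), ])
  expect_equal(es2$time, es$time)
  # single read maps to the origin
  expect_equal(export_event_stream(d[1, ])$time, 0)
})

test_that("glance methods summarize each stage", {
  d <- load_format(finch_reads())
  v <- visits(d)
  expect_equal(glance(d)$n_reads, 10)
  expect_equal(glance(v)$n_visits, 4)
  p <- presence(v)
  expect_equal(glance(p)$n_bouts, 2)
  m <- movements(finch_visits())
  expect_equal(glance(m)$n_movements, 3)
})
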