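# Independent brute-force re-derivations of the gap-rule
# transformations, written as plain nested loops so they share no code
# path with the package implementations.

secs <- function(a, b) as.numeric(difftime(a, b, units = "secs"))

bf_visits <- function(d, bw = 3) {
  d <- d[order(d$animal_id, d$time), ]
  out <- list()
  for (a in unique(d$animal_id)) {
    da <- d[d$animal_id == a, ]
    i <- 1
    while (i <= nrow(da)) {
      j <- i
      while (j < nrow(da) &&
        da$logger_id[j + 1] == da$logger_id[j] &&
        secs(da$time[j + 1], da$time[j]) < bw) {
        j <- j + 1
      }
      out[[length(out) + 1]] <- data.frame(
        animal_id = a, logger_id = da$logger_id[i],
        start = da$time[i], end = da$time[j]
      )
      i <- j + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(animal_id = character(), logger_id = character(),
      start = d$time[0], end = d$time[0]))
  }
  res <- do.call(rbind, out)
  res[order(res$animal_id, res$start), ]
}

bf_presence <- function(v, bw = 15) {
  v <- v[order(v$animal_id, v$start), ]
  out <- list()
  for (a in unique(v$animal_id)) {
    va <- v[v$animal_id == a, ]
    i <- 1
    while (i <= nrow(va)) {
      j <- i
      while (j < nrow(va) &&
        va$logger_id[j + 1] == va$logger_id[j] &&
        secs(va$start[j + 1], va$end[j]) < bw * 60) {
        j <- j + 1
      }
      out[[length(out) + 1]] <- data.frame(
        animal_id = a, logger_id = va$logger_id[i],
        start = va$start[i], end = va$end[j],
        length = secs(va$end[j], va$start[i]) / 60
      )
      i <- j + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(animal_id = character(), logger_id = character(),
      start = v$start[0], end = v$start[0], length = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$animal_id, res$start), ]
}

bf_movements <- function(v) {
  v <- v[order(v$animal_id, v$start), ]
  out <- list()
  for (a in unique(v$animal_id)) {
    va <- v[v$animal_id == a, ]
    if (nrow(va) < 2) next
    id <- 0
    for (i in 2:nrow(va)) {
      if (va$logger_id[i] != va$logger_id[i - 1]) {
        id <- id + 1
        dt <- secs(va$start[i], va$end[i - 1])
        out[[length(out) + 1]] <- data.frame(
          animal_id = a, move_id = id,
          left_logger = va$logger_id[i - 1],
          left_time = va$end[i - 1],
          arrived_logger = va$logger_id[i],
          arrived_time = va$start[i],
          strength = 3600 / dt
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(animal_id = character(), move_id = integer(),
      left_logger = character(), left_time = v$start[0],
      arrived_logger = character(), arrived_time = v$start[0],
      strength = numeric()))
  }
  do.call(rbind, out)
}

bf_displacements <- function(v, bw = 2) {
  out <- list()
  for (lg in unique(v$logger_id)) {
    vl <- v[v$logger_id == lg, ]
    vl <- vl[order(vl$start, vl$end, vl$animal_id), ]
    if (nrow(vl) < 2) next
    for (i in 2:nrow(vl)) {
      gap <- secs(vl$start[i], vl$end[i - 1])
      if (vl$animal_id[i] != vl$animal_id[i - 1] && gap >= 0 && gap < bw) {
        out[[length(out) + 1]] <- data.frame(
          logger_id = lg,
          displacee = vl$animal_id[i - 1],
          displacer = vl$animal_id[i],
          displacer_start = vl$start[i],
          gap_seconds = gap
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(logger_id = character(), displacee = character(),
      displacer = character(), displacer_start = v$start[0],
      gap_seconds = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$displacer_start, res$logger_id), ]
}

expect_same_events <- function(got, want, cols) {
  expect_equal(nrow(got), nrow(want))
  for (cc in cols) {
    g <- got[[cc]]
    w <- want[[cc]]
    if (inherits(g, "POSIXct")) {
      expect_equal(as.numeric(g), as.numeric(w))
    } else {
      expect_equal(unname(g), unname(w), tolerance = 1e-12)
    }
  }
}
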