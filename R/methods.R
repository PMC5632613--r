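# tidy()/glance()/autoplot() methods for the result classes.

#' @exportS3Method generics::glance
glance.perch_reads <- function(x, ...) {
  tibble(
    n_reads = nrow(x),
    n_animals = n_distinct(x$animal_id),
    n_loggers = n_distinct(x$logger_id),
    first = if (nrow(x)) min(x$time) else as.POSIXct(NA),
    last = if (nrow(x)) max(x$time) else as.POSIXct(NA)
  )
}

#' @exportS3Method generics::glance
glance.perch_visits <- function(x, ...) {
  tibble(
    n_visits = nrow(x),
    n_animals = n_distinct(x$animal_id),
    n_loggers = n_distinct(x$logger_id),
    total_visit_min = sum(secs_between(x$end, x$start)) / 60
  )
}

#' @exportS3Method generics::glance
glance.perch_presence <- function(x, ...) {
  tibble(
    n_bouts = nrow(x),
    n_animals = n_distinct(x$animal_id),
    n_loggers = n_distinct(x$logger_id),
    total_presence_min = sum(as.numeric(x$length))
  )
}

#' @exportS3Method generics::glance
glance.perch_movements <- function(x, ...) {
  tibble(
    n_movements = nrow(x),
    n_animals = n_distinct(x$animal_id),
    n_paths = n_distinct(x$move_path),
    mean_strength = if (nrow(x)) mean(x$strength) else NA_real_
  )
}

#' @exportS3Method generics::glance
glance.perch_interactions <- function(x, ...) {
  tibble(
    n_events = nrow(x$sequence),
    n_animals = nrow(x$matrix)
  )
}

#' @exportS3Method generics::tidy
tidy.perch_interactions <- function(x, ...) {
  long <- as.data.frame.table(x$matrix, responseName = "n",
    stringsAsFactors = FALSE)
  out <- as_tibble(long)
  names(out) <- c("winner", "loser", "n")
  arrange(filter(out, .data$winner != .data$loser),
    .data$winner, .data$loser)
}

#' @exportS3Method ggplot2::autoplot
autoplot.perch_daily <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$time_of_day / 60, y = .data$p_active)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$animal_id)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6),
      limits = c(0, 24)) +
    ggplot2::labs(x = "Hour of day",
      y = "Proportion of days active") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.perch_activity <- function(object, ...) {
  tz <- attr(object, "tz") %||% tz_of(object$bin_start)
  d <- as_tibble(object)
  d$day <- lubridate::as_date(d$bin_start, tz = tz)
  d$tod <- secs_after_midnight(d$bin_start) / 3600
  ggplot2::ggplot(d,
    ggplot2::aes(x = .data$tod, y = .data$day,
      fill = factor(.data$active))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$animal_id)) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "red4"),
      name = "Active") +
    ggplot2::labs(x = "Hour of day", y = "Day") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.perch_presence <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(y = .data$animal_id, colour = .data$logger_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
      yend = .data$animal_id), linewidth = 3) +
    ggplot2::labs(x = NULL, y = NULL, colour = "Logger") +
    ggplot2::theme_minimal()
}
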