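#' Map styling parameters
#'
#' Controls how presence amounts map to node sizes and path use to
#' edge widths on the summary map, with a shared yellow-to-red color
#' ramp (low to high). `p_scale` / `m_scale` multiply the node and
#' edge display ranges for quick tweaks without restating the ranges.
#'
#' @param node_size Node display size range `c(min, max)` in mm.
#' @param edge_width Edge linewidth range `c(min, max)` in mm.
#' @param low,high Ends of the color ramp.
#' @param p_scale,m_scale Multiplicative tweaks on the two ranges.
#' @param p_title,m_title Legend titles for presence and movements.
#' @return A `perch_map_style` list.
#' @export
map_style <- function(node_size = c(3, 12), edge_width = c(0.5, 4),
                      low = "yellow", high = "red",
                      p_scale = 1, m_scale = 1,
                      p_title = "Total time (min)",
                      m_title = "Path use") {
  for (rng in list(node_size, edge_width)) {
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2]) {
      abort("size/width ranges must be positive with min <= max",
        class = "perchflow_spec_error")
    }
  }
  if (p_scale <= 0 || m_scale <= 0) {
    abort("p_scale and m_scale must be positive",
      class = "perchflow_spec_error")
  }
  structure(
    list(node_size = node_size, edge_width = edge_width,
      low = low, high = high, p_scale = p_scale, m_scale = m_scale,
      p_title = p_title, m_title = m_title),
    class = "perch_map_style"
  )
}

#' Linearly map amounts onto a display range
#'
#' `[min(values), max(values)]` maps linearly onto `[lo, hi]`;
#' all-equal inputs map to the midpoint of the range.
#'
#' @param values Non-negative amounts.
#' @param range Display range `c(lo, hi)`.
#' @return Numeric vector of display sizes.
#' @examples
#' scale_to_style(c(0, 5, 10), c(2, 20))
#' @export
scale_to_style <- function(values, range) {
  if (any(is.na(values))) {
    abort("values must not contain NA", class = "perchflow_input_error")
  }
  if (any(values < 0)) {
    abort("values must be non-negative", class = "perchflow_input_error")
  }
  lo <- range[1]
  hi <- range[2]
  span <- max(values) - min(values)
  if (length(values) == 0) return(numeric())
  if (span == 0) {
    return(rep((lo + hi) / 2, length(values)))
  }
  lo + (values - min(values)) / span * (hi - lo)
}

#' Build the presence/movement network map
#'
#' Stations are drawn at their coordinates, with a circle sized and
#' colored by presence amount (small yellow = little time, large red =
#' much time) and straight edges between path endpoints weighted and
#' colored by path use (narrow yellow = rarely used, wide red =
#' heavily used). Small black points always mark the station
#' locations themselves. Axes are in degrees with an equal-aspect
#' (quick map) projection. Returns the ggplot object;
#' [render_summary_map()] writes it to an image file.
#'
#' @param ps Presence summary from [summarize_presence()] (needs
#'   `logger_id`, `lat`, `lon`, `amount`).
#' @param ms Movement summary from [summarize_movements()] (needs
#'   `move_path`, `lat_1`, `lon_1`, `lat_2`, `lon_2`, `path_use`), or
#'   `NULL`.
#' @param style A [map_style()].
#' @param allow_empty_moves Permit a nodes-only map when `ms` is
#'   missing or empty?
#' @param background Optional basemap: list with `path` to a PNG and
#'   geographic bounds `xmin`, `xmax`, `ymin`, `ymax`.
#' @return A ggplot object.
#' @export
plot_summary_map <- function(ps, ms = NULL, style = map_style(),
                             allow_empty_moves = FALSE,
                             background = NULL) {
  require_columns(ps, c("logger_id", "lat", "lon", "amount"),
    what = "presence summary")
  ps <- as_tibble(ps)
  no_moves <- is.null(ms) || nrow(ms) == 0
  if (nrow(ps) == 0 && no_moves) {
    abort("nothing to draw: empty presence and movement summaries",
      class = "perchflow_input_error")
  }
  if (no_moves && !allow_empty_moves) {
    abort(paste0("movement summary is empty; pass allow_empty_moves ",
      "= TRUE for a nodes-only map"), class = "perchflow_input_error")
  }
  missing_nodes <- unique(ps$logger_id[is.na(ps$lat) | is.na(ps$lon)])
  if (length(missing_nodes) > 0) {
    abort(sprintf("loggers without coordinates: %s",
      paste(missing_nodes, collapse = ", ")),
    class = "perchflow_input_error")
  }
  if (!no_moves) {
    require_columns(ms, c("move_path", "lat_1", "lon_1", "lat_2", "lon_2",
      "path_use"), what = "movement summary")
    ms <- as_tibble(ms)
    bad <- is.na(ms$lat_1) | is.na(ms$lon_1) | is.na(ms$lat_2) |
      is.na(ms$lon_2)
    if (any(bad)) {
      abort(sprintf("paths without endpoint coordinates: %s",
        paste(unique(ms$move_path[bad]), collapse = ", ")),
      class = "perchflow_input_error")
    }
  }
  if (any(ps$amount < 0) || (!no_moves && any(ms$path_use < 0))) {
    abort("amounts and path use must be non-negative",
      class = "perchflow_input_error")
  }

  gg <- ggplot2::ggplot()
  if (!is.null(background)) {
    img <- png::readPNG(background$path)
    gg <- gg + ggplot2::annotation_raster(img,
      xmin = background$xmin, xmax = background$xmax,
      ymin = background$ymin, ymax = background$ymax)
  }
  if (!no_moves) {
    gg <- gg +
      ggplot2::geom_segment(
        data = ms,
        ggplot2::aes(x = .data$lon_1, y = .data$lat_1,
          xend = .data$lon_2, yend = .data$lat_2,
          linewidth = .data$path_use, colour = .data$path_use),
        lineend = "round"
      ) +
      ggplot2::scale_linewidth(
        range = style$edge_width * style$m_scale, name = style$m_title) +
      ggplot2::scale_colour_gradient(
        low = style$low, high = style$high, name = style$m_title)
  }
  gg <- gg +
    ggplot2::geom_point(
      data = ps,
      ggplot2::aes(x = .data$lon, y = .data$lat, size = .data$amount,
        fill = .data$amount),
      shape = 21, colour = "grey30", alpha = 0.85
    ) +
    ggplot2::scale_size(
      range = style$node_size * style$p_scale, name = style$p_title) +
    ggplot2::scale_fill_gradient(
      low = style$low, high = style$high, name = style$p_title) +
    ggplot2::geom_point(
      data = distinct(ps, .data$logger_id, .data$lat, .data$lon),
      ggplot2::aes(x = .data$lon, y = .data$lat),
      colour = "black", size = 1
    ) +
    ggplot2::guides(
      size = ggplot2::guide_legend(title = style$p_title),
      fill = ggplot2::guide_legend(title = style$p_title)
    ) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
  gg
}

#' Render the summary map to an image file
#'
#' @inheritParams plot_summary_map
#' @param out Output image path (extension selects the device;
#'   `.png` recommended).
#' @param width,height,dpi Image geometry passed to [ggplot2::ggsave()].
#' @return `out`, invisibly.
#' @export
render_summary_map <- function(ps, ms = NULL, style = map_style(),
                               out = "map.png",
                               allow_empty_moves = FALSE,
                               background = NULL,
                               width = 7, height = 6, dpi = 150) {
  gg <- plot_summary_map(ps, ms, style = style,
    allow_empty_moves = allow_empty_moves, background = background)
  ggplot2::ggsave(out, gg, width = width, height = height, dpi = dpi)
  invisible(out)
}
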