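#' Apply a transformation independently within groups
#'
#' Field deployments often hold several experiments or sites whose
#' detection streams must never mix: a movement or bout spanning two
#' experiments would be an artifact. `apply_grouped()` splits a table
#' on the given key columns, applies a transformation to each piece
#' independently, and binds the results with the keys re-attached.
#' `animal_n` (and hence per-individual averages) is computed within
#' each group.
#'
#' Any pipeline stage can be grouped: `"visits"`, `"displacements"`
#' (alias `"disp"`), `"movements"` (alias `"move"`), `"presence"`,
#' `"activity"` (alias for [activity_grid()]), `"daily"`,
#' `"summarize_presence"`, `"summarize_movements"`.
#'
#' @param d Input table for the chosen stage.
#' @param keys Character vector of grouping column names in `d`.
#' @param stage Transformation name (above).
#' @param ... Passed to the stage function (e.g. `bw = `).
#' @return The stage's output with the key columns attached; class as
#'   the ungrouped stage would return.
#' @examples
#' \dontrun{
#' v <- apply_grouped(reads, "experiment", "visits", bw = 3)
#' m <- apply_grouped(v, "experiment", "movements")
#' }
#' @export
apply_grouped <- function(d, keys, stage, ...) {
  stages <- list(
    visits = visits,
    displacements = displacements,
    disp = displacements,
    movements = movements,
    move = movements,
    presence = presence,
    activity = activity_grid,
    daily = daily_pattern,
    summarize_presence = summarize_presence,
    summarize_movements = summarize_movements
  )
  if (!is.character(stage) || length(stage) != 1 ||
    !stage %in% names(stages)) {
    abort(sprintf("unknown stage '%s'; one of: %s",
      paste(stage, collapse = ","),
      paste(unique(names(stages)), collapse = ", ")),
    class = "perchflow_spec_error")
  }
  require_columns(d, keys, what = "grouped input")
  fn <- stages[[stage]]
  tz <- attr(d, "tz")

  keyframe <- distinct(as_tibble(d)[, keys, drop = FALSE])
  keyframe <- arrange(keyframe, across(all_of(keys)))
  pieces <- vector("list", nrow(keyframe))
  for (i in seq_len(nrow(keyframe))) {
    sel <- rep(TRUE, nrow(d))
    for (k in keys) sel <- sel & (d[[k]] == keyframe[[k]][i])
    piece <- as_tibble(d)[sel, setdiff(names(d), keys), drop = FALSE]
    attr(piece, "tz") <- tz
    res <- fn(piece, ...)
    cls <- class(res)
    for (k in keys) res[[k]] <- keyframe[[k]][i]
    res <- select(res, all_of(keys), dplyr::everything())
    class(res) <- cls
    pieces[[i]] <- res
  }
  out <- bind_rows(pieces)
  if (length(pieces) > 0) class(out) <- class(pieces[[1]])
  attr(out, "tz") <- tz
  out
}
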