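#' Parse a timestamp order specification
#'
#' Detection files come with many timestamp dialects. A time spec is a
#' compact order string over the letters `y` (year), `m` (month), `d`
#' (day), `H` (hour), `M` (minute), `S` (second) and `p` (AM/PM
#' marker), e.g. `"ymd HMS"` or `"dmy HM p"`. The spec fixes only the
#' token order; separators (`-`, `/`, `:`, `.`, space) and 2- vs
#' 4-digit years are handled flexibly by the parser built from it.
#' Two-digit years use the standard POSIX pivot (69-99 -> 1900s,
#' 00-68 -> 2000s), so `"31-12-17"` under `"dmy"` is 2017-12-31.
#'
#' @param spec Order string; letters from `y m d H M S p`, each at most
#'   once, whitespace ignored.
#' @return A `perch_time_spec` object: the validated token order plus
#'   the order string handed to the datetime parser.
#' @examples
#' parse_time_spec("dmy HM p")
#' parse_timestamps("31-12-17 09:12 pm", parse_time_spec("dmy HM p"))
#' @export
parse_time_spec <- function(spec) {
  if (inherits(spec, "perch_time_spec")) {
    return(spec)
  }
  if (!is.character(spec) || length(spec) != 1 || is.na(spec)) {
    abort("time spec must be a single string such as \"ymd HMS\"",
      class = "perchflow_spec_error")
  }
  letters_seq <- strsplit(gsub("\\s+", "", spec), "")[[1]]
  allowed <- c(
    y = "year", m = "month", d = "day",
    H = "hour", M = "minute", S = "second", p = "ampm"
  )
  unknown <- setdiff(letters_seq, names(allowed))
  if (length(unknown) > 0) {
    abort(sprintf("unknown time spec token: '%s'", unknown[1]),
      class = "perchflow_spec_error")
  }
  dup <- letters_seq[duplicated(letters_seq)]
  if (length(dup) > 0) {
    abort(sprintf("repeated time spec token: '%s'", dup[1]),
      class = "perchflow_spec_error")
  }
  tokens <- unname(allowed[letters_seq])
  for (needed in c("year", "month", "day")) {
    if (!needed %in% tokens) {
      abort(sprintf("time spec must contain a %s token", needed),
        class = "perchflow_spec_error")
    }
  }
  if ("minute" %in% tokens && !"hour" %in% tokens) {
    abort("time spec token 'M' (minute) requires 'H' (hour)",
      class = "perchflow_spec_error")
  }
  if ("ampm" %in% tokens && !"hour" %in% tokens) {
    abort("time spec token 'p' (AM/PM) requires 'H' (hour)",
      class = "perchflow_spec_error")
  }
  structure(
    list(tokens = tokens, order = paste(letters_seq, collapse = "")),
    class = "perch_time_spec"
  )
}

#' @export
print.perch_time_spec <- function(x, ...) {
  cat("<time spec> ", paste(x$tokens, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Parse timestamp strings under a time spec
#'
#' @param x Character vector of timestamps.
#' @param spec A spec string or [parse_time_spec()] result.
#' @param tz IANA timezone name the timestamps are local to.
#' @return POSIXct vector, `NA` where a value does not parse (impossible
#'   calendar values such as month 13 are `NA`, not recycled).
#' @export
parse_timestamps <- function(x, spec = "ymd HMS", tz = "UTC") {
  spec <- parse_time_spec(spec)
  if (!tz %in% OlsonNames()) {
    abort(sprintf("unknown timezone: '%s'", tz),
      class = "perchflow_spec_error")
  }
  x <- as.character(x)
  out <- lubridate::parse_date_time(x, orders = spec$order, tz = tz,
    quiet = TRUE)
  lubridate::floor_date(out, "second")
}
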