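Package: perchflow
Title: Transform and Map Detection Streams from Static Logger Stations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for loading, transforming, summarizing and mapping
    time-stamped, georeferenced detection data collected at static
    stations, such as RFID-enabled bird feeders reading PIT tags.
    Raw per-logger files or pre-formatted tables are consolidated into
    visits with a gap rule, then derived into displacements (dominance
    proxies), station-to-station movements weighted by inverse travel
    time, presence bouts, binary activity grids and average daily
    activity patterns. Includes visualization summaries with static
    network maps, export adapters for dominance and association
    analyses, a ground-truth-aware detection simulator, and a command
    line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
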