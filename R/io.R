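# Plain-text serialization of recordings and results. A recording round-
# trips through a directory of CSV files (traces, events, cell table) plus
# a JSON protocol/metadata pair with a schema version, so recordings can be
# regenerated, inspected and diffed without binary formats.

SC_SCHEMA_VERSION <- "1.0"

#' Write a recording to a directory of CSV/JSON files
#'
#' @param recording An `sc_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(t(recording$traces)),
                   file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(recording$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(recording$cells),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  p <- recording$protocol
  jsonlite::write_json(
    list(schema_version = SC_SCHEMA_VERSION,
         frame_rate_hz = recording$frame_rate_hz,
         seed = recording$seed,
         protocol = list(kind = p$kind, n_repeats = p$n_repeats,
                         seed = p$seed, conditions = p$conditions,
                         order = p$order)),
    file.path(dir, "recording.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns", na = "null")
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory containing `traces.csv`, `events.csv`, `cells.csv`
#'   and `recording.json`.
#' @return An `sc_recording`.
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$schema_version, SC_SCHEMA_VERSION)) {
    stop("unsupported recording schema version: ", meta$schema_version,
         call. = FALSE)
  }
  traces <- t(as.matrix(utils::read.csv(file.path(dir, "traces.csv"),
                                        check.names = FALSE)))
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  rownames(traces) <- cells$cell_id
  cond <- as.data.frame(meta$protocol$conditions)
  ord <- as.data.frame(meta$protocol$order)
  protocol <- structure(list(kind = meta$protocol$kind,
                             conditions = cond,
                             n_repeats = meta$protocol$n_repeats,
                             order = ord,
                             seed = meta$protocol$seed),
                        class = "sc_protocol")
  structure(list(traces = traces,
                 frame_rate_hz = meta$frame_rate_hz,
                 events = utils::read.csv(file.path(dir, "events.csv")),
                 protocol = protocol,
                 cells = cells,
                 seed = meta$seed),
            class = "sc_recording")
}

#' Write a per-cell results table to CSV
#'
#' @param results An `sc_cell_summary` (or any data frame).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cell_summary <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
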