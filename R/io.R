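#' Read and write tab-separated trial tables
#'
#' Trial logs, schedules and protocol tables are stored as tab-separated
#' text with a single header line.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `read_trial_table()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read and write raw traces as CSV
#'
#' Two-column CSV (`time`, `value`); event timestamps travel in a
#' separate table via [write_trial_table()] or as YAML/JSON.
#'
#' @param trace Tibble with `time` and `value`.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a run manifest
#'
#' Serializes agent parameters and seeds of a simulated protocol to a
#' JSON manifest alongside the trial table.
#'
#' @param protocol An `rl_protocol`.
#' @param path File path.
#' @export
write_run_manifest <- function(protocol, path) {
  stopifnot(inherits(protocol, "rl_protocol"))
  jsonlite::write_json(
    list(params = unclass(protocol$params), seed = protocol$seed,
         rules = protocol$rules,
         converged = as.list(protocol$converged),
         package_version = as.character(utils::packageVersion("ruleswitch"))),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
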