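# File formats: the measurement-records CSV dialect (comma separated, UTF-8,
# header row, ISO 8601 timestamps) and structured reports (JSON for single
# results, CSV for tables).

#' Read measurement records from CSV
#'
#' Expected columns: `trip_id`, `haul_id`, `haul_datetime` (ISO 8601, UTC),
#' `haul_catch_kg`, `length_cm`, `n_measured`, `raising_factor`. Validation
#' failures name the offending row and column.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated records data.frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.record_cols, names(raw))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  dt <- as.POSIXct(raw$haul_datetime, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  bad <- which(is.na(dt) & !is.na(raw$haul_datetime))
  if (length(bad))
    stop(sprintf("unparsable timestamp in column 'haul_datetime' at row %d",
                 bad[1L]))
  raw$haul_datetime <- dt
  .validate_records(raw[, .record_cols])
}

#' Write measurement records to CSV
#'
#' Inverse of [read_records()]; timestamps are written as ISO 8601 UTC so a
#' round trip reproduces the records exactly.
#'
#' @param records A records data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  .validate_records(records)
  out <- records[, .record_cols]
  out$haul_datetime <- format(out$haul_datetime, "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a structured report for a result object
#'
#' Single results (`dissimilarity`, `reference_result`, `scenario_result`,
#' `bootstrap_comparison`) are serialized to JSON with the `D` decomposition
#' itemized; tables (`grid_result` or any data.frame) go to CSV.
#'
#' @param x A result object.
#' @param path Output path (`.json` or `.csv` by type).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  UseMethod("write_report")
}

#' @export
write_report.dissimilarity <- function(x, path) {
  jsonlite::write_json(
    list(l1 = x$l1, penalty_dim = x$penalty_dim,
         penalty_shift = x$penalty_shift,
         penalty_amplitude = x$penalty_amplitude,
         total_D = x$total_D,
         conditions = as.list(x$condition_flags)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
write_report.reference_result <- function(x, path) {
  jsonlite::write_json(
    list(adv = x$adv, iterations_accepted = x$iterations_accepted,
         removed_total = x$removed_total,
         stopping_reason = x$stopping_reason,
         reference = list(classes = x$reference$classes,
                          counts = x$reference$counts),
         trace = x$trace),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
write_report.scenario_result <- function(x, path) {
  jsonlite::write_json(
    list(description = x$description, D = x$D, adv = x$adv,
         admissible = x$admissible, sizes = x$sizes,
         mean_length = x$mean_length, se_mean_length = x$se_mean_length,
         replicates = x$replicates),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
write_report.bootstrap_comparison <- function(x, path) {
  jsonlite::write_json(
    list(grand_mean_D = x$grand_mean_D, replicates = x$replicates,
         n_boot = x$n_boot, by_cell = x$by_cell),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
write_report.data.frame <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
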