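# Plain-text interchange: CSV trial tables, CSV eye traces, JSON summaries.

#' Read and write trial-record tables
#'
#' Trial tables travel as plain CSV with the fixed column dictionary
#' (participant, block, instruction, disruption, hemifield_fear, choice,
#' latency_ms, qc, and any extra columns present).
#'
#' @param table a trial-record data.frame.
#' @param file path to a CSV file.
#' @return `read_trial_table()` returns the data.frame;
#'   `write_trial_table()` returns `file` invisibly.
#' @export
write_trial_table <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Read an eye trace from CSV
#'
#' Expects columns `time_ms` and `x_deg` (uniform 1 kHz sampling).
#'
#' @param file path to a CSV file.
#' @param stim_onset_ms stimulus onset within the trace (ms).
#' @return An `eye_trace` object.
#' @export
read_eye_trace <- function(file, stim_onset_ms) {
  df <- utils::read.csv(file)
  stopifnot(all(c("time_ms", "x_deg") %in% names(df)))
  structure(list(time_ms = df$time_ms, x_deg = df$x_deg,
                 stim_onset_ms = stim_onset_ms, truth = list(onset_ms = NA)),
            class = "eye_trace")
}

#' Write a QC summary as JSON
#'
#' @param qc_summary the `qc_summary` element of [build_trial_table()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_qc_summary <- function(qc_summary, file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing JSON requires the jsonlite package")
  jsonlite::write_json(qc_summary, file, auto_unbox = TRUE)
  invisible(file)
}
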