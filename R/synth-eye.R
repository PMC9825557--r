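#' Synthesize a 1 kHz horizontal eye-position trace for one trial
#'
#' Builds a fixture trace for the saccade detector: Gaussian sensor noise
#' around fixation, then -- unless the record is an absent trial -- a
#' minimum-jerk sigmoidal displacement to the chosen face's eccentricity
#' starting at the record's latency. Optionally a slow pre-stimulus drift is
#' added to emulate inadequate fixation. The true onset, direction and QC
#' label are stored in the trace for recovery tests.
#'
#' @param record one trial-record row (needs `latency_ms`, `direction`, `qc`;
#'   `choice == "none"` or `qc == "absent"` gives a no-saccade trace).
#' @param noise_sd_deg sensor noise SD in degrees (default 0.1).
#' @param sac_duration_ms saccade duration (default 40 ms).
#' @param seed integer seed for the trace noise.
#' @param eccentricity_deg saccade amplitude (default 5.3).
#' @param pre_ms,post_ms trace extent around stimulus onset.
#' @param bad_fixation if TRUE, a slow sinusoidal drift (1.5 deg) corrupts the
#'   pre-stimulus fixation window.
#' @return An object of class `eye_trace`: `time_ms`, `x_deg`,
#'   `stim_onset_ms`, and a `truth` list.
#' @export
synth_eye_trace <- function(record, noise_sd_deg = 0.1, sac_duration_ms = 40,
                            seed = 1L, eccentricity_deg = 5.3,
                            pre_ms = 300, post_ms = 1500,
                            bad_fixation = FALSE) {
  if (noise_sd_deg < 0) stop("noise_sd_deg must be >= 0")
  n <- as.integer(pre_ms + post_ms)
  t <- seq_len(n) - 1
  x <- numeric(n)
  absent <- is.na(record$latency_ms) || record$choice == "none" ||
    record$qc == "absent"
  onset <- if (absent) NA_real_ else pre_ms + record$latency_ms
  if (!absent) {
    sgn <- if (record$direction == "R") 1 else -1
    tau <- pmin(pmax((t - onset) / sac_duration_ms, 0), 1)
    x <- sgn * eccentricity_deg * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  }
  if (bad_fixation) {
    x <- x + 2 * sin(2 * pi * t / 300) # slow ocular instability, ~2 deg
  }
  if (noise_sd_deg > 0) x <- x + with_seed(seed, rnorm(n, 0, noise_sd_deg))
  structure(list(
    time_ms = t, x_deg = x, stim_onset_ms = pre_ms,
    truth = list(onset_ms = onset,
                 direction = if (absent) NA_character_ else record$direction,
                 qc = if (bad_fixation) "bad_fixation" else record$qc)),
    class = "eye_trace")
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("eye_trace: %d samples at 1 kHz, stimulus at %g ms", length(x$x_deg),
              x$stim_onset_ms))
  if (!is.na(x$truth$onset_ms))
    cat(sprintf(", true saccade onset %g ms", x$truth$onset_ms))
  cat("\n")
  invisible(x)
}

#' Synthesize eye traces for a whole cohort, with optional QC corruption
#'
#' Wraps [synth_eye_trace()] over a trial table and optionally converts a
#' fraction of trials into QC failures with known labels: absent (no
#' saccade), implausibly fast (latency redrawn in 60-90 ms), and inadequate
#' pre-stimulus fixation. The realized per-trial QC truth is returned in the
#' `qc_true` column of the updated table.
#'
#' @param records trial table from [simulate_behaviour()].
#' @param noise_sd_deg sensor noise SD (degrees).
#' @param seed master seed; per-trial substreams are derived from it.
#' @param qc_fractions named fractions of trials to corrupt, e.g.
#'   `c(absent = 0.05, too_fast = 0.03, bad_fixation = 0.05)`.
#' @param eccentricity_deg saccade amplitude.
#' @return list with `traces` (list of `eye_trace`) and `records` (table with
#'   `qc_true`).
#' @export
synth_eye_cohort <- function(records, noise_sd_deg = 0.1, seed = 1L,
                             qc_fractions = c(absent = 0, too_fast = 0,
                                              bad_fixation = 0),
                             eccentricity_deg = 5.3) {
  n <- nrow(records)
  records$trial_uid <- records$trial_uid %||% seq_len(n)
  u <- with_seed(substream_seeds(seed, 2^21)[1], runif(n))
  f_ab <- qc_fractions["absent"] %||% 0
  f_tf <- qc_fractions["too_fast"] %||% 0
  f_bf <- qc_fractions["bad_fixation"] %||% 0
  corrupt <- ifelse(u < f_ab, "absent",
                    ifelse(u < f_ab + f_tf, "too_fast",
                           ifelse(u < f_ab + f_tf + f_bf, "bad_fixation", "none")))
  tseed <- substream_seeds(seed, 2^22 + records$trial_uid)
  traces <- vector("list", n)
  qc_true <- character(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    bf <- FALSE
    if (corrupt[i] == "absent") {
      r$choice <- "none"; r$qc <- "absent"; r$latency_ms <- NA_real_
    } else if (corrupt[i] == "too_fast") {
      r$latency_ms <- 60 + 30 * with_seed(tseed[i] + 1L, runif(1))
      r$qc <- "too_fast"
      if (is.na(r$direction)) r$direction <- "R"
    } else if (corrupt[i] == "bad_fixation") {
      bf <- TRUE
    }
    traces[[i]] <- synth_eye_trace(r, noise_sd_deg = noise_sd_deg,
                                   seed = tseed[i],
                                   eccentricity_deg = eccentricity_deg,
                                   bad_fixation = bf)
    qc_true[i] <- traces[[i]]$truth$qc
  }
  records$qc_true <- qc_true
  list(traces = traces, records = records)
}
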