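#' Calibrate the injected gamma burst against the spectral estimator
#'
#' The burst amplitude is specified as a percent increase over baseline band
#' power, so the generator measures -- with the package's own multitaper
#' estimator -- (a) the baseline power of the pink-noise background at the
#' burst frequency and (b) the estimator's peak response to a unit-amplitude
#' burst, and converts the requested percentage into a carrier amplitude.
#' This keeps the injected and recovered percent-change scales identical by
#' construction.
#'
#' @param truth a [ground_truth()] (uses `truth$lfp_burst`).
#' @param seed seed for the calibration noise draws.
#' @param fs sampling rate (Hz).
#' @param noise_sd background noise SD (arbitrary units).
#' @param n_cal number of calibration noise epochs.
#' @return `truth` with `lfp_burst$amplitude_abs` (carrier amplitude) set.
#' @export
synth_lfp_calibrate <- function(truth, seed = 1L, fs = 1024, noise_sd = 1,
                                n_cal = 20) {
  b <- truth$lfp_burst
  toi <- seq(-0.8, 0.8, by = 0.025)
  p_noise <- 0
  for (i in seq_len(n_cal)) {
    x <- pink_noise(6 * fs, fs, noise_sd,
                    seed = substream_seeds(seed, 2^23 + i))
    tf <- tfr_spectrogram(x, band = "high", fs = fs, t0 = -2, toi = toi)
    fi <- which.min(abs(tf$freq - b$freq_hz))
    base <- tf$time >= -0.6 & tf$time <= -0.2
    p_noise <- p_noise + mean(tf$power[fi, base])
  }
  p_noise <- p_noise / n_cal
  xb <- burst_waveform(6 * fs, fs, b, amplitude = 1, phase = 0)
  tfb <- tfr_spectrogram(xb, band = "high", fs = fs, t0 = -2, toi = toi)
  fi <- which.min(abs(tfb$freq - b$freq_hz))
  gain <- max(tfb$power[fi, ]) # estimator response per unit amplitude^2
  truth$lfp_burst$amplitude_abs <-
    sqrt((b$amplitude_pct / 100) * p_noise / gain)
  truth$lfp_burst$noise_sd <- noise_sd
  truth
}

# 1/f (pink) background noise with unit-variance scaling, via spectral
# shaping of white Gaussian noise; the spectrum is flattened below 1 Hz.
pink_noise <- function(n, fs, sd = 1, seed = NULL) {
  gen <- function() {
    f <- seq(0, fs / 2, length.out = n %/% 2 + 1)
    amp <- 1 / sqrt(pmax(f, 1))
    re <- rnorm(length(amp)); im <- rnorm(length(amp))
    spec <- complex(real = re * amp, imaginary = im * amp)
    spec[1] <- 0
    full <- c(spec, Conj(rev(spec[2:(n - length(spec) + 1)])))
    x <- Re(stats::fft(full, inverse = TRUE))
    sd * x / stats::sd(x)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Gaussian-windowed sinusoid at the burst parameters; time 0 is stimulus
# onset, the epoch starts at -2 s.
burst_waveform <- function(n, fs, b, amplitude, phase) {
  t <- seq(0, n - 1) / fs - 2
  env <- exp(-(t - b$center_ms / 1000)^2 / (2 * (b$sd_ms / 1000)^2))
  amplitude * env * cos(2 * pi * b$freq_hz * t + phase)
}

#' Synthesize one local field potential epoch
#'
#' A 6 s (-2 to +4 s around stimulus onset) single-channel epoch at 1024 Hz:
#' pink (1/f) background noise plus, on trials where gaze oriented to the
#' face contralateral to the recording side, an amplitude-modulated burst at
#' the ground-truth gamma frequency with random carrier phase per trial
#' (induced, not phase-locked, activity).
#'
#' @param record one trial-record row (needs `choice`, `hemifield_fear`,
#'   `electrode_side`).
#' @param truth a [ground_truth()] passed through [synth_lfp_calibrate()].
#' @param seed integer seed for this epoch.
#' @param fs sampling rate (Hz; default 1024).
#' @return An object of class `lfp_epoch`: samples `x`, `fs`, epoch start
#'   `t0`, condition labels and the ground-truth burst indicator.
#' @export
synth_lfp_epoch <- function(record, truth, seed = 1L, fs = 1024) {
  b <- truth$lfp_burst
  if (is.null(b$amplitude_abs))
    stop("burst not calibrated; run synth_lfp_calibrate() first")
  n <- 6 * fs
  # recording side relative to the fearful face, and orientation target
  side <- if (record$hemifield_fear == record$electrode_side) "Ipsi" else "Contra"
  oriented_hemifield <- if (record$choice == "fear") record$hemifield_fear
    else setdiff(c("L", "R"), record$hemifield_fear)
  contra_orient <- oriented_hemifield != record$electrode_side
  x <- pink_noise(n, fs, b$noise_sd %||% 1, seed = seed)
  if (contra_orient && b$amplitude_abs > 0) {
    phase <- with_seed(seed + 1L, runif(1, 0, 2 * pi))
    x <- x + burst_waveform(n, fs, b, b$amplitude_abs, phase)
  }
  structure(list(x = x, fs = fs, t0 = -2,
                 participant = record$participant,
                 recording_side = side,
                 emotion = record$choice,
                 truth = list(burst = contra_orient)),
            class = "lfp_epoch")
}

#' @export
print.lfp_epoch <- function(x, ...) {
  cat(sprintf("lfp_epoch: %d samples at %g Hz (%g to %g s), side %s, emotion %s\n",
              length(x$x), x$fs, x$t0, x$t0 + length(x$x) / x$fs,
              x$recording_side, x$emotion))
  invisible(x)
}

#' Synthesize the LFP epochs of a cohort's analysable trials
#'
#' Calibrates the burst once, then generates one epoch per Yield undisrupted
#' trial with a definite orientation (the trials entering the induced
#' time-frequency analysis; disrupted blocks carry stimulation artefact and
#' are excluded by design).
#'
#' @param records trial table from [simulate_behaviour()].
#' @param truth a [ground_truth()].
#' @param seed master seed.
#' @param fs sampling rate.
#' @return list with `epochs` and the corresponding `records` subset.
#' @export
synth_lfp_cohort <- function(records, truth, seed = 1L, fs = 1024) {
  truth <- synth_lfp_calibrate(truth, seed = seed, fs = fs)
  keep <- records$instruction == "Yield" & records$disruption == "None" &
    records$qc == "valid" & records$choice %in% c("fear", "neutral")
  rec <- records[keep, , drop = FALSE]
  rec$recording_side <- ifelse(rec$hemifield_fear == rec$electrode_side,
                               "Ipsi", "Contra")
  rec$trial_uid <- rec$trial_uid %||% seq_len(nrow(rec))
  eseed <- substream_seeds(seed, 2^24 + rec$trial_uid)
  epochs <- lapply(seq_len(nrow(rec)), function(i)
    synth_lfp_epoch(rec[i, ], truth, seed = eseed[i], fs = fs))
  list(epochs = epochs, records = rec, truth = truth)
}
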