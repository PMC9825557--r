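test_that("a noise-only trace yields no saccades", {
  tr <- fx_trace(onsets_ms = numeric(0), amps_deg = numeric(0),
                 noise_sd = 0.05, seed = 2)
  expect_equal(nrow(detect_saccades(tr)), 0)
})

test_that("a clean movement is detected with an accurate onset", {
  tr <- fx_trace(onsets_ms = 550, amps_deg = 5.3, noise_sd = 0.1, seed = 5)
  sac <- detect_saccades(tr)
  expect_equal(nrow(sac), 1)
  expect_lt(abs(sac$onset_ms - 550), 5)
  expect_identical(sac$direction, "right")
  expect_gt(sac$amplitude_deg, 5)
})

test_that("each printed criterion excludes candidates individually", {
  # amplitude: a 0.3 deg movement is supra-threshold in velocity but small
  small <- fx_trace(onsets_ms = 550, amps_deg = 0.3)
  expect_equal(nrow(detect_saccades(small)), 0)
  # duration: same amplitude compressed into 10 ms fails the 20 ms rule
  fast <- fx_trace(onsets_ms = 550, amps_deg = 0.9, dur_ms = 8)
  expect_equal(nrow(detect_saccades(fast)), 0)
  # velocity: a 1 deg drift over a full second never crosses 5 deg/s
  slow <- fx_trace(onsets_ms = 400, amps_deg = 1, dur_ms = 1000)
  expect_equal(nrow(detect_saccades(slow)), 0)
  # fixation: two movements separated by 30 ms -> second rejected
  two <- fx_trace(onsets_ms = c(500, 570), amps_deg = c(2, 2))
  sac <- detect_saccades(two)
  expect_equal(nrow(sac), 1)
  expect_lt(abs(sac$onset_ms - 500), 5)
  # the same two movements 80 ms apart are both kept
  two_ok <- fx_trace(onsets_ms = c(500, 620), amps_deg = c(2, 2))
  expect_equal(nrow(detect_saccades(two_ok)), 2)
})

test_that("tightening any criterion never increases the detection count", {
  base <- saccade_criteria()
  tighter <- list(
    saccade_criteria(min_velocity_deg_s = 30),
    saccade_criteria(min_amplitude_deg = 2),
    saccade_criteria(min_fixation_ms = 200),
    saccade_criteria(min_duration_ms = 35))
  for (s in 1:20) {
    tr <- fx_trace(onsets_ms = c(400, 700), amps_deg = c(5.3, -5.3),
                   noise_sd = 0.1, seed = s)
    n0 <- nrow(detect_saccades(tr, base))
    for (cr in tighter) expect_lte(nrow(detect_saccades(tr, cr)), n0)
  }
})

test_that("non-uniform or too-short traces are refused", {
  tr <- fx_trace(onsets_ms = 550, amps_deg = 5.3)
  tr$time_ms <- tr$time_ms * 2
  expect_error(detect_saccades(tr), "uniform")
  expect_error(detect_saccades(list(time_ms = 0:20, x_deg = rnorm(21))),
               "short")
})

test_that("scoring applies the printed QC rules", {
  meta <- data.frame(hemifield_fear = "L")
  # latency 90 ms -> too fast
  tr <- fx_trace(onsets_ms = 390, amps_deg = -5.3)
  rec <- score_trial(tr, detect_saccades(tr), meta)
  expect_identical(rec$qc, "too_fast")
  expect_true(is.na(rec$latency_ms))
  # no saccade within 1000 ms -> absent, choice "none"
  tr <- fx_trace(onsets_ms = 1500, amps_deg = 5.3)
  rec <- score_trial(tr, detect_saccades(tr), meta)
  expect_identical(rec$qc, "absent")
  expect_identical(rec$choice, "none")
  # leftward saccade with the fearful face on the left -> fear
  tr <- fx_trace(onsets_ms = 550, amps_deg = -5.3)
  rec <- score_trial(tr, detect_saccades(tr), meta)
  expect_identical(rec$qc, "valid")
  expect_identical(rec$choice, "fear")
  expect_equal(rec$latency_ms, 250, tolerance = 0.03)
  expect_error(score_trial(tr, detect_saccades(tr), data.frame(x = 1)),
               "metadata")
})

test_that("scoring is a pure function of trace and criteria", {
  tr <- fx_trace(onsets_ms = 550, amps_deg = 5.3, noise_sd = 0.1, seed = 3)
  meta <- data.frame(hemifield_fear = "R")
  r1 <- score_trial(tr, detect_saccades(tr), meta)
  r2 <- score_trial(tr, detect_saccades(tr), meta)
  expect_identical(r1, r2)
})

test_that("the trial table accounts exactly and matches QC ground truth", {
  d <- fx_design_small()
  tr <- fx_truth()
  b <- simulate_behaviour(d, tr, seed = 5)
  co <- synth_eye_cohort(b[1:150, ], seed = 6,
                         qc_fractions = c(absent = 0.08, too_fast = 0.05,
                                          bad_fixation = 0.06))
  res <- build_trial_table(co$traces, co$records)
  qs <- res$qc_summary
  expect_equal(qs$acquired, 150)
  expect_equal(qs$remaining, qs$acquired - qs$rejected)
  expect_identical(res$table$qc, co$records$qc_true)
  # an all-valid set is not rejected at all
  co2 <- synth_eye_cohort(b[b$qc == "valid", ][1:40, ], seed = 7)
  res2 <- build_trial_table(co2$traces, co2$records)
  expect_equal(res2$qc_summary$rejected, 0)
  expect_error(build_trial_table(co2$traces,
                                 transform(co2$records, trial_uid = 1)),
               "duplicate")
})

test_that("detected latencies and choices recover the generator's", {
  d <- fx_design_small()
  tr <- fx_truth()
  b <- simulate_behaviour(d, tr, seed = 8)
  b <- b[b$qc == "valid", ][1:60, ]
  co <- synth_eye_cohort(b, seed = 9)
  res <- build_trial_table(co$traces, co$records)
  v <- res$table$qc == "valid"
  expect_gte(mean(v), 0.95)
  err <- res$table$latency_ms[v] - co$records$latency_ms[v]
  expect_gte(mean(abs(err) <= 10), 0.95)
  expect_lt(max(abs(err)), 25)
  expect_identical(res$table$choice[v], co$records$choice[v])
})
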