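test_that("the trial list conserves counts and carries one level per factor", {
  d <- make_design(design_spec(n_participants = 1, blocks_per_condition = 1,
                               trials_per_block = 50, seed = 3))
  # 4 block conditions (Instruction x Presence) x 50 trials
  expect_equal(nrow(d), 200)
  expect_equal(unname(table(d$block))[1], 50)
  expect_true(all(d$instruction %in% c("Yield", "Oppose")))
  expect_true(all(d$disruption %in% c("None", "Ipsi", "Contra")))
  expect_true(all(d$hemifield_fear %in% c("L", "R")))
  expect_false(any(is.na(d$instruction)))
  # laterality labels only in disrupted blocks
  expect_true(all(d$disruption[!d$disrupted] == "None"))
  expect_true(all(d$disruption[d$disrupted] != "None"))
})

test_that("fixation durations stay within the stated jitter range", {
  d <- fx_design_full()
  expect_true(all(d$fixation_ms >= 1500 & d$fixation_ms <= 2000))
})

test_that("the design is deterministic given the seed", {
  d1 <- make_design(design_spec(n_participants = 2, seed = 5))
  d2 <- make_design(design_spec(n_participants = 2, seed = 5))
  d3 <- make_design(design_spec(n_participants = 2, seed = 6))
  expect_identical(d1, d2)
  expect_false(identical(d1$hemifield_fear, d3$hemifield_fear))
})

test_that("fearful-face side is marginally balanced", {
  d <- fx_design_full()
  n <- nrow(d)
  expect_gt(stats::binom.test(sum(d$hemifield_fear == "R"), n, 0.5)$p.value,
            0.01)
})

test_that("invalid design specifications are refused", {
  expect_error(design_spec(trials_per_block = 0), "trials_per_block")
  expect_error(design_spec(jitter_ms = -1), "jitter")
  expect_error(design_spec(instruction_levels = c("A", "B")), "instruction")
})

test_that("ground-truth link offsets reproduce the target contrasts exactly", {
  tr <- fx_truth()
  expect_equal(unname(tr$contrasts$ddm["z_laterality_yield"]), -0.104,
               tolerance = 1e-8)
  expect_equal(unname(tr$contrasts$ddm["t0_disruption_presence"]), 19,
               tolerance = 1e-8)
  expect_equal(unname(tr$contrasts$ddm["a_instruction"]), 0.194,
               tolerance = 1e-8)
  expect_equal(unname(tr$contrasts$latency["laterality_x_f3_yield"]), 17,
               tolerance = 1e-6)
  expect_equal(unname(tr$contrasts$latency["instruction_x_laterality_x_f3"]),
               -22, tolerance = 1e-6)
  expect_equal(unname(tr$contrasts$choice["laterality_x_f3_yield"]), -0.15,
               tolerance = 1e-6)
})

test_that("behaviour generation is deterministic and conserves trials", {
  d <- fx_design_small()
  tr <- fx_truth()
  b1 <- simulate_behaviour(d, tr, seed = 4)
  b2 <- simulate_behaviour(d, tr, seed = 4)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), nrow(d))
  expect_true(all(b1$latency_ms > 0))
})

test_that("per-trial substreams survive subsetting of the design", {
  d <- fx_design_small()
  tr <- fx_truth()
  full <- simulate_behaviour(d, tr, seed = 4)
  sub <- simulate_behaviour(d[51:120, ], tr, seed = 4)
  expect_equal(sub$latency_ms, full$latency_ms[51:120])
  expect_equal(sub$choice, full$choice[51:120])
})

test_that("symmetric ground truth gives a balanced fear-choice rate", {
  tr0 <- ground_truth(ddm = list(v0 = 0, dz_lat_yield = 0,
                                 dz_instruction_x_lat = 0,
                                 da_instruction = 0, dt0_presence = 0),
                      subject_sd = 0)
  d <- make_design(design_spec(n_participants = 5, blocks_per_condition = 5,
                               seed = 9))
  b <- simulate_behaviour(d, tr0, seed = 10)
  b <- b[b$qc == "valid", ]
  n <- nrow(b)
  expect_gte(n, 4800)
  expect_gt(stats::binom.test(sum(b$choice == "fear"), n, 0.5)$p.value, 0.01)
  expect_gt(stats::binom.test(sum(b$direction == "R"), n, 0.5)$p.value, 0.01)
})

test_that("a lowered start point lowers the fear-choice rate in that cell", {
  tr <- fx_truth()
  d <- make_design(design_spec(n_participants = 6, blocks_per_condition = 3,
                               seed = 13))
  b <- simulate_behaviour(d, tr, seed = 14)
  b <- b[b$qc == "valid" & b$instruction == "Yield", ]
  rate_contra <- mean(b$choice[b$disruption == "Contra"] == "fear")
  rate_none <- mean(b$choice[b$disruption == "None"] == "fear")
  expect_lt(rate_contra, rate_none)
})

test_that("a non-decision shift moves the whole latency distribution", {
  tr <- fx_truth()
  d <- fx_design_small()
  b <- simulate_behaviour(d, tr, seed = 15)
  t0_none <- tr$ddm$t00 * 1000
  expect_gt(min(b$latency_ms[b$disrupted], na.rm = TRUE), t0_none)
})

test_that("latency-mode and choice-mode generators honour their cells", {
  tr <- fx_truth()
  d <- fx_design_full()
  bl <- simulate_behaviour(d, tr, seed = 16, generator = "latency")
  expect_true(all(bl$latency_ms > tr$latency$delta0 * exp(-4 * tr$subject_sd)))
  expect_identical(bl$emotion, bl$choice)
  bc <- simulate_behaviour(d, tr, seed = 17, generator = "choice")
  expect_true(all(bc$latbin[bc$qc == "valid"] %in% c("Early", "Late")))
  # early trials prefer the fearful face under the generating truth
  v <- bc[bc$qc == "valid", ]
  expect_gt(mean(v$choice[v$latbin == "Early"] == "fear"),
            mean(v$choice[v$latbin == "Late"] == "fear"))
})
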