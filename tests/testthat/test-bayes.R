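test_that("median split is computed independently within factorial cells", {
  tab <- data.frame(
    instruction = rep(c("Yield", "Oppose"), each = 4),
    disruption = "None", hemifield_fear = "L",
    latency_ms = c(200, 300, 400, 500, 150, 250, 350, 450),
    qc = "valid", stringsAsFactors = FALSE)
  out <- median_split(tab)
  expect_identical(out$latbin[1:4], c("Early", "Early", "Late", "Late"))
  # different medians across cells: equal latencies get different labels
  expect_identical(out$latbin[tab$latency_ms == 350], "Late")
  tab2 <- tab[tab$instruction == "Yield", ][1:3, ]
  out2 <- median_split(tab2)
  # odd cell: the median value itself goes Late
  expect_identical(out2$latbin, c("Early", "Late", "Late"))
  # per-cell Early/Late counts differ by at most one
  d <- fx_design_small()
  b <- simulate_behaviour(d, fx_truth(), seed = 19)
  ms <- median_split(b)
  ms <- ms[ms$qc == "valid", ]
  key <- paste(ms$instruction, ms$disruption, ms$hemifield_fear)
  for (k in unique(key)) {
    cnt <- table(ms$latbin[key == k])
    expect_lte(abs(cnt["Early"] - cnt["Late"]), 1)
  }
  expect_error(median_split(transform(tab, qc = "absent")), "cell")
})

test_that("posterior contrast summaries behave on constructed draws", {
  pos <- rep(2, 1000)
  sym <- c(seq(-1, -0.001, length.out = 500), seq(0.001, 1, length.out = 500))
  s1 <- amygaze:::summarize_contrast(pos)
  expect_equal(s1$p_effect, 1.0)
  s2 <- amygaze:::summarize_contrast(sym)
  expect_equal(s2$p_effect, 0.5)
  expect_lte(s2$ci_low, s2$mean)
  expect_lte(s2$mean, s2$ci_high)
  nrm <- withr::with_seed(1, rnorm(2e5))
  s3 <- amygaze:::summarize_contrast(nrm)
  expect_equal(s3$ci_low, -1.96, tolerance = 0.02)
  expect_equal(s3$ci_high, 1.96, tolerance = 0.02)
})

test_that("diagnostics recognise converged and unconverged draws", {
  set.seed(2)
  iid <- array(rnorm(2000 * 4 * 2), c(2000, 4, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  dg <- diagnostics(iid)
  expect_true(all(dg$rhat < 1.01))
  expect_true(all(abs(dg$ess - 8000) / 8000 < 0.2))
  stuck <- array(rep(c(0, 5), each = 1000), c(1000, 2, 1),
                 dimnames = list(NULL, NULL, "a"))
  dg2 <- diagnostics(stuck)
  expect_gt(dg2$rhat, 1.01)
  expect_false(dg2$pass)
  expect_error(diagnostics(iid[, 1, , drop = FALSE]), "two chains")
})

test_that("an undersampled fit raises a convergence error", {
  d <- fx_design_small()
  b <- simulate_behaviour(d, fx_truth(), seed = 20, generator = "choice")
  expect_error(
    fit_behaviour(b, "choice", seed = 1,
                  sampler = sampler_options(chains = 2, iter = 220,
                                            burn = 100, thin = 1)),
    class = "amyg_convergence_error")
})

test_that("latencies simulated from the priors are physiological", {
  set.seed(30)
  n <- 2000
  mu <- rnorm(n, log(250), 1)
  sigma <- exp(rnorm(n, log(0.3), 1))
  delta <- exp(rnorm(n, log(100), 1))
  lat <- delta + rlnorm(n, mu, sigma)
  expect_gt(mean(lat > 0 & lat <= 2000), 0.85)
})

test_that("a reduced latency fit recovers its generating contrasts", {
  d <- fx_design_full()
  tr <- fx_truth()
  b <- simulate_behaviour(d, tr, seed = 41, generator = "latency")
  f <- fit_behaviour(b, "latency", seed = 41, sampler = fx_sampler())
  pc <- planned_contrasts(f)
  expect_equal(nrow(pc), 5)
  expect_true(all(pc$ci_low <= pc$mean & pc$mean <= pc$ci_high))
  truth <- tr$contrasts$latency[pc$contrast]
  covered <- pc$ci_low <= truth & truth <= pc$ci_high
  expect_gte(sum(covered), 4)
  # the injected interaction has the right sign
  expect_gt(pc$mean[pc$contrast == "laterality_x_f3_yield"], 0)
  # link-scale domains: sigma and delta positive in every draw
  dm <- amygaze:::draw_matrix(f)
  expect_true(all(exp(dm[, "log_sigma0"]) > 0))
  expect_true(all(exp(dm[, "log_delta0"]) > 0))
})

test_that("a reduced choice fit stays on the rate scale and covers truth", {
  d <- fx_design_full()
  tr <- fx_truth()
  b <- simulate_behaviour(d, tr, seed = 43, generator = "choice")
  f <- fit_behaviour(b, "choice", seed = 43, sampler = fx_sampler())
  pc <- planned_contrasts(f)
  truth <- tr$contrasts$choice[pc$contrast]
  expect_gte(sum(pc$ci_low <= truth & truth <= pc$ci_high), 4)
  cd <- amygaze:::cell_draws(f, "theta")
  expect_true(all(cd$values > 0 & cd$values < 1))
  # a contrast addressing the confound directly is refused
  expect_error(contrast(f, "hemifield", 1), "confound")
})

test_that("a reduced drift-diffusion fit covers its generating effects", {
  d <- fx_design_full()
  tr <- fx_truth()
  b <- simulate_behaviour(d, tr, seed = 45)
  f <- fit_behaviour(b, "ddm", seed = 45,
                     sampler = fx_sampler(chains = 5, iter = 6000, burn = 2000,
                                          thin = 4))
  pc <- planned_contrasts(f)
  z <- pc[pc$contrast == "z_laterality_yield", ]
  t0 <- pc[pc$contrast == "t0_disruption_presence", ]
  expect_true(z$ci_low <= -0.104 && -0.104 <= z$ci_high)
  expect_true(t0$ci_low <= 19 && 19 <= t0$ci_high)
  expect_lt(z$mean, 0)
  expect_gt(t0$mean, 0)
  # z draws respect the unit interval, a and t0 are positive
  expect_true(all(amygaze:::cell_draws(f, "z")$values > 0 &
                    amygaze:::cell_draws(f, "z")$values < 1))
  expect_true(all(amygaze:::cell_draws(f, "a")$values > 0))
  expect_true(all(amygaze:::cell_draws(f, "t0")$values > 0))
})

test_that("hemifield marginalization is neutral when the effect is absent", {
  # the generator places no hemifield effect; compare the Yield laterality
  # contrast computed marginally with the same contrast within one
  # hemifield's cells (ddm cells carry hemifield explicitly)
  d <- fx_design_full()
  tr <- fx_truth()
  b <- simulate_behaviour(d, tr, seed = 47)
  f <- fit_behaviour(b, "ddm", seed = 47,
                     sampler = fx_sampler(chains = 4, iter = 4000, burn = 1800,
                                          thin = 3))
  cells <- f$cells$cells_vz
  w_marg <- amygaze:::contrast_defs_vz(cells)$laterality_yield
  one_side <- function(h) {
    w <- numeric(nrow(cells))
    sel <- cells$hemifield == h
    w[cells$instruction == "Yield" & cells$disruption == "Contra" & sel] <- 1
    w[cells$instruction == "Yield" & cells$disruption == "Ipsi" & sel] <- -1
    w
  }
  cm <- contrast(f, "z", w_marg)
  cl <- contrast(f, "z", one_side("L"))
  cr <- contrast(f, "z", one_side("R"))
  # equal-weight marginalization is exactly the mean of the per-hemifield
  # contrasts (native scale, linear weights)
  expect_equal(cm$mean, (cl$mean + cr$mean) / 2, tolerance = 1e-10)
  # with no generating hemifield effect the two sides agree within noise
  expect_lt(abs(cl$mean - cr$mean), 3 * (cl$ci_high - cl$ci_low) / 1.96)
})

test_that("fit methods expose the posterior coherently", {
  d <- fx_design_small()
  tr <- fx_truth()
  b <- simulate_behaviour(d, tr, seed = 49, generator = "choice")
  f <- fit_behaviour(b, "choice", seed = 49,
                     sampler = fx_sampler(iter = 3000, burn = 1200))
  expect_output(print(f), "Bernoulli")
  sm <- summary(f)
  expect_true(all(c("mean", "ci_low", "rhat") %in% names(sm$fixed)))
  expect_named(coef(f))
  pr <- predict(f)
  expect_true(all(pr$mean > 0 & pr$mean < 1))
  reps <- simulate(f, nsim = 2, seed = 1)
  expect_length(reps, 2)
  expect_true(all(reps[[1]]$choice %in% c("fear", "neutral")))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(f))
})
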