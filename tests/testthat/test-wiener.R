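test_that("zero-drift absorption probability equals the start point", {
  expect_equal(choice_prob_upper(wiener_params(0, 2, 0.5, 0)), 0.5)
  expect_equal(choice_prob_upper(wiener_params(0, 2, 0.3, 0)), 0.3)
  expect_equal(choice_prob_upper(wiener_params(0, 0.7, 0.81, 0.1)), 0.81)
})

test_that("closed-form choice probability matches Monte-Carlo absorption", {
  p <- wiener_params(1, 2, 0.5, 0)
  sim <- simulate_ddm(p, 2e4, seed = 42, method = "euler", dt = 1e-4)
  phat <- mean(sim$upper)
  p0 <- choice_prob_upper(p)
  se <- sqrt(p0 * (1 - p0) / 2e4)
  expect_lt(abs(phat - p0), 3 * se)
})

test_that("density is zero at and below the non-decision time", {
  p <- wiener_params(0.5, 1.2, 0.4, 0.25)
  expect_equal(wfpt_density(c(0.1, 0.25), p, "upper"), c(0, 0))
  expect_gt(wfpt_density(0.4, p, "upper"), 0)
})

test_that("upper and lower defective densities integrate to one", {
  for (par in list(c(1, 2, 0.4, 0.1), c(-2, 0.8, 0.6, 0), c(0, 1.5, 0.3, 0.2))) {
    p <- wiener_params(par[1], par[2], par[3], par[4])
    iu <- integrate(function(t) wfpt_density(t, p, "upper"), p$t0, Inf,
                    rel.tol = 1e-9)$value
    il <- integrate(function(t) wfpt_density(t, p, "lower"), p$t0, Inf,
                    rel.tol = 1e-9)$value
    expect_lt(abs(iu + il - 1), 1e-6)
    expect_lt(abs(iu - choice_prob_upper(p)), 1e-6)
  }
})

test_that("small-time and large-time expansions agree in their overlap", {
  worst <- 0
  for (w in seq(0.1, 0.9, by = 0.2)) {
    for (v in c(-5, -1, 0, 2, 5)) {
      for (a in c(0.5, 1, 2, 4)) {
        p <- wiener_params(v, a, w, 0)
        tg <- a^2 * seq(0.05, 2, by = 0.1) # normalized times 0.05..2
        ds <- wfpt_density(tg, p, "upper", eps = 1e-14, method = "small")
        dl <- wfpt_density(tg, p, "upper", eps = 1e-14, method = "large")
        worst <- max(worst, max(abs(ds - dl)))
      }
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("boundary relabeling symmetry holds exactly", {
  t <- seq(0.05, 2, by = 0.05)
  p1 <- wiener_params(1.3, 1.7, 0.35, 0)
  p2 <- wiener_params(-1.3, 1.7, 0.65, 0)
  expect_identical(wfpt_density(t, p1, "upper"), wfpt_density(t, p2, "lower"))
})

test_that("log-likelihood is consistent with the density and its domain", {
  p <- wiener_params(0.8, 1.4, 0.45, 0.2)
  one <- data.frame(choice = "fear", rt = 0.6)
  expect_equal(wfpt_loglik(one, p), log(wfpt_density(0.6, p, "upper")))
  bad <- data.frame(choice = c("fear", "neutral"), rt = c(0.6, 0.15))
  expect_identical(wfpt_loglik(bad, p), -Inf)
  expect_error(wfpt_loglik(data.frame(choice = character(0), rt = numeric(0)), p),
               "empty")
})

test_that("simulators agree with each other at the median", {
  p <- wiener_params(1, 2, 0.5, 0.1)
  se <- simulate_ddm(p, 4e4, seed = 8, method = "euler", dt = 1e-4)
  sh <- simulate_ddm(p, 4e4, seed = 9, method = "exact_hybrid")
  expect_lt(abs(median(se$rt[se$upper]) - median(sh$rt[sh$upper])), 0.004)
  expect_true(all(se$rt > p$t0))
  expect_true(all(sh$rt > p$t0))
  expect_error(simulate_ddm(p, 0), "positive")
})

test_that("maximum likelihood on simulated trials recovers the parameters", {
  p <- wiener_params(1.5, 1.4, 0.4, 0.25)
  sim <- simulate_ddm(p, 2000, seed = 31)
  n <- nrow(sim)
  nll <- function(th) {
    -wfpt_loglik_cpp(sim$rt, as.integer(sim$upper), rep(th[1], n),
                     rep(exp(th[2]), n), rep(plogis(th[3]), n),
                     rep(exp(th[4]), n))
  }
  o <- optim(c(0, 0, 0, log(0.15)), nll, method = "BFGS")
  est <- c(o$par[1], exp(o$par[2]), plogis(o$par[3]), exp(o$par[4]))
  expect_lt(abs(est[1] - p$v) / p$v, 0.05)
  expect_lt(abs(est[2] - p$a) / p$a, 0.05)
  expect_lt(abs(est[3] - p$z) / p$z, 0.05)
  expect_lt(abs(est[4] - p$t0) / p$t0, 0.05)
})

test_that("invalid parameters are rejected", {
  expect_error(wiener_params(1, -1, 0.5, 0), "a")
  expect_error(wiener_params(1, 1, 1.2, 0), "z")
  expect_error(wiener_params(1, 1, 0.5, -0.1), "t0")
})
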