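# Shared fixtures: built once per test run, all generated in code.

fx <- new.env()

fx_truth <- function() {
  if (is.null(fx$truth)) fx$truth <- ground_truth()
  fx$truth
}

fx_design_small <- function() {
  if (is.null(fx$design_small))
    fx$design_small <- make_design(design_spec(n_participants = 2, seed = 7))
  fx$design_small
}

fx_design_full <- function() {
  if (is.null(fx$design_full))
    fx$design_full <- make_design(design_spec(seed = 11))
  fx$design_full
}

# quick reduced-draw sampler for unit-test fits
fx_sampler <- function(chains = 4, iter = 4000, burn = 1500, thin = 3) {
  sampler_options(chains = chains, iter = iter, burn = burn, thin = thin,
                  check = FALSE)
}

# a minimum-jerk trace built outside the generator, for detector tests
fx_trace <- function(onsets_ms, amps_deg, dur_ms = 40, n = 1800,
                     stim_ms = 300, noise_sd = 0, seed = 1) {
  x <- numeric(n)
  t <- seq_len(n) - 1
  for (i in seq_along(onsets_ms)) {
    tau <- pmin(pmax((t - onsets_ms[i]) / dur_ms[min(i, length(dur_ms))], 0), 1)
    x <- x + amps_deg[i] * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  }
  if (noise_sd > 0) x <- x + withr::with_seed(seed, rnorm(n, 0, noise_sd))
  structure(list(time_ms = t, x_deg = x, stim_onset_ms = stim_ms,
                 truth = list(onset_ms = onsets_ms[1])), class = "eye_trace")
}
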