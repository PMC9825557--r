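#' Drift-diffusion parameter set
#'
#' Bundles the four parameters of the Wiener diffusion model of two-choice
#' decisions under the unit-diffusion scaling convention: drift rate `v`
#' (evidence per second, positive towards the upper boundary, coded here as
#' orientation to the fearful face), boundary separation `a` (> 0), relative
#' start point `z` (in (0, 1); 0.5 is unbiased) and non-decision time `t0`
#' (seconds, >= 0), absorbing sensory and motor delays.
#'
#' @param v drift rate (evidence/s, positive towards the fear boundary).
#' @param a boundary separation (> 0).
#' @param z relative start point, strictly between 0 and 1.
#' @param t0 non-decision time in seconds (>= 0).
#' @return An object of class `wiener_params`.
#' @examples
#' p <- wiener_params(v = 1, a = 1.5, z = 0.5, t0 = 0.15)
#' choice_prob_upper(p)
#' @export
wiener_params <- function(v, a, z, t0) {
  stopifnot(is.numeric(v), length(v) == 1, is.finite(v))
  if (!is.numeric(a) || a <= 0) stop("boundary separation `a` must be > 0")
  if (!is.numeric(z) || z <= 0 || z >= 1) stop("start point `z` must lie in (0, 1)")
  if (!is.numeric(t0) || t0 < 0) stop("non-decision time `t0` must be >= 0")
  structure(list(v = v, a = a, z = z, t0 = t0), class = "wiener_params")
}

#' @export
print.wiener_params <- function(x, ...) {
  cat(sprintf("Wiener parameters: v = %.3f, a = %.3f, z = %.3f, t0 = %.3f s\n",
              x$v, x$a, x$z, x$t0))
  invisible(x)
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form hitting probability of the upper boundary for a Wiener
#' diffusion with unit diffusion coefficient,
#' \eqn{P = (1 - e^{-2vaz}) / (1 - e^{-2va})}, reducing to `z` when `v = 0`.
#'
#' @param p a [wiener_params()] object.
#' @return The probability, in (0, 1), that the process is absorbed at the
#'   upper (fear) boundary.
#' @export
choice_prob_upper <- function(p) {
  stopifnot(inherits(p, "wiener_params"))
  choice_prob_upper_cpp(p$v, p$a, p$z)
}

#' Wiener first-passage-time density
#'
#' Defective density of the first passage through one boundary, evaluated at
#' stimulus-locked times `t` (the density is zero for `t <= t0`). The density
#' integrates over `(t0, Inf)` to that boundary's hitting probability; the two
#' boundaries together integrate to one. Internally the standardized density
#' is computed by a small-time or large-time series expansion, switched
#' automatically by the standard accuracy criterion; `method` can force a
#' branch, which is useful for checking the expansions against each other in
#' their overlap region.
#'
#' @param t numeric vector of times (seconds).
#' @param p a [wiener_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @param eps series truncation tolerance.
#' @param method `"auto"`, `"small"` or `"large"`.
#' @return Numeric vector of densities (1/s).
#' @export
wfpt_density <- function(t, p, boundary = c("upper", "lower"), eps = 1e-10,
                         method = c("auto", "small", "large")) {
  stopifnot(inherits(p, "wiener_params"), is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative")
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  m <- match(method, c("auto", "small", "large")) - 1L
  wfpt_density_cpp(t, p$v, p$a, p$z, p$t0, boundary == "upper", eps, m)
}

#' Joint log-likelihood of choices and latencies under the Wiener model
#'
#' Sums per-trial log first-passage densities, mapping fear choices to the
#' upper boundary. Any latency at or below `t0` contributes `-Inf`.
#'
#' @param trials a data frame with columns `choice` (`"fear"`/`"neutral"` or
#'   logical/0-1 upper-boundary indicator) and `rt` (seconds).
#' @param p a [wiener_params()] object.
#' @return The log-likelihood (scalar).
#' @export
wfpt_loglik <- function(trials, p) {
  stopifnot(inherits(p, "wiener_params"), is.data.frame(trials))
  if (nrow(trials) == 0) stop("empty trial list")
  up <- trials$choice
  if (is.character(up) || is.factor(up)) up <- as.character(up) == "fear"
  up <- as.integer(up)
  n <- nrow(trials)
  wfpt_loglik_cpp(trials$rt, up, rep(p$v, n), rep(p$a, n), rep(p$z, n),
                  rep(p$t0, n))
}

#' Simulate choices and response times from the Wiener model
#'
#' `method = "euler"` integrates the stochastic differential equation with an
#' Euler-Maruyama scheme of step `dt`; `method = "exact_hybrid"` draws the
#' boundary from the closed-form hitting probability and the decision time by
#' inverting the numerically integrated first-passage distribution. The two
#' methods are mutual oracles: their RT quantiles agree to within the Euler
#' discretization error.
#'
#' @param p a [wiener_params()] object.
#' @param n number of trials (> 0).
#' @param seed optional integer seed.
#' @param method `"exact_hybrid"` (default) or `"euler"`.
#' @param dt Euler time step (s), or inversion grid step for the hybrid
#'   sampler.
#' @return A data frame with columns `choice` (`"fear"`/`"neutral"`), `rt`
#'   (seconds) and `upper` (logical).
#' @export
simulate_ddm <- function(p, n, seed = NULL,
                         method = c("exact_hybrid", "euler"), dt = NULL) {
  stopifnot(inherits(p, "wiener_params"))
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive count")
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (method == "euler") {
    if (is.null(dt)) dt <- 1e-4
    sim <- sim_ddm_euler_cpp(as.integer(n), p$v, p$a, p$z, p$t0, dt, 60)
  } else {
    if (is.null(dt)) dt <- 2.5e-4
    sim <- sim_ddm_hybrid_cpp(as.integer(n), p$v, p$a, p$z, p$t0, dt)
  }
  data.frame(choice = ifelse(sim$upper == 1L, "fear", "neutral"),
             rt = sim$rt, upper = sim$upper == 1L,
             stringsAsFactors = FALSE)
}
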