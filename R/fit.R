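#' Fit a hierarchical Bayesian model of saccadic behaviour
#'
#' Fits one of the three behavioural models to a QC-filtered trial table:
#'
#' * `"latency"`: saccadic latency as a shifted lognormal whose location
#'   `mu` varies with Instruction x Disruption x Emotion (fully factorial)
#'   plus the fearful-face hemifield as a confound; log-scale SD `sigma` and
#'   shift `delta` (the earliest possible response) carry intercepts only.
#' * `"choice"`: binary orientation choice as a Bernoulli with
#'   fear-preference rate `theta` (logit link) varying with Instruction x
#'   Disruption x binarized Latency, plus the hemifield confound. The table
#'   must carry (or will be given) a within-cell median-split `latbin`.
#' * `"ddm"`: choice and latency jointly under the Wiener drift-diffusion
#'   likelihood; drift `v` and start point `z` (logit link) vary with
#'   Instruction x Disruption(3) x Hemifield, boundary separation `a` and
#'   non-decision time `t0` (log links) with Instruction x Disruption
#'   presence. `delta` is bounded above by 95% of each participant's fastest
#'   valid latency; `t0` by each participant's fastest latency in the trials
#'   its cell governs (the first-passage density vanishes smoothly there).
#'
#' Every parameter has participant random intercepts drawn from a
#' hierarchical Normal prior (partial pooling), with
#' weakly-informative priors throughout: standard-Normal fixed effects per
#' link scale, half-Normal(0,1) random-intercept SDs. Posteriors are drawn
#' by DE-MCz ([sampler_options()]); fits failing the split R-hat / ESS gate
#' raise a convergence error unless `sampler$check` is disabled.
#'
#' @param table trial-record data.frame (only `qc == "valid"` rows are used).
#' @param model `"latency"`, `"choice"` or `"ddm"`.
#' @param priors named list of prior overrides (see the model builders).
#' @param sampler a [sampler_options()] object; `NULL` picks the model's
#'   default (the drift-diffusion posterior needs substantially longer
#'   chains than the two generalized linear models; expect a couple of
#'   minutes for a gated `"ddm"` fit).
#' @param seed integer seed for the sampler.
#' @return An object of class `amyg_fit` with posterior draws (iterations x
#'   chains x parameters), the cell structure used for contrasts, and a
#'   convergence report.
#' @seealso [planned_contrasts()], [contrast()], [diagnostics()]
#' @export
fit_behaviour <- function(table, model = c("latency", "choice", "ddm"),
                          priors = list(), sampler = NULL,
                          seed = 1L) {
  model <- match.arg(model)
  if (is.null(sampler)) {
    sampler <- switch(model,
      ddm = sampler_options(chains = 8, iter = 32000, burn = 5000, thin = 12),
      latency = sampler_options(chains = 6, iter = 12000, burn = 3000, thin = 3),
      choice = sampler_options(chains = 6, iter = 8000, burn = 2500, thin = 4))
  }
  stopifnot(inherits(sampler, "sampler_options"))
  if (model == "choice" && is.null(table$latbin)) table <- median_split(table)
  m <- switch(model,
              latency = build_latency_model(table, priors),
              choice = build_choice_model(table, priors),
              ddm = build_wiener_model(table, priors))

  K <- sampler$chains
  d <- length(m$init)
  set.seed(seed)
  # Laplace pre-step: find the posterior mode and its local Gaussian
  # approximation. The archive of difference-vector proposals is seeded
  # from it (correctly scaled and correlated from the first iteration) and
  # the fixed-effect blocks get conditional refresh proposals from it.
  neg <- function(x) {
    v <- -drop(m$logpost(matrix(x, 1)))
    if (!is.finite(v)) 1e10 else v # keep BFGS finite at constraint edges
  }
  o <- stats::optim(m$init, neg, method = "BFGS",
                    control = list(maxit = 300, reltol = 1e-7))
  H <- stats::optimHess(o$par, neg)
  H <- (H + t(H)) / 2
  ei <- eigen(H, symmetric = TRUE)
  # clip eigenvalues to an absolute sane band: a finite-difference probe
  # that falls off a constraint edge contaminates one direction with an
  # enormous eigenvalue, and a relative floor would then crush every other
  # direction with it
  lam <- pmin(pmax(ei$values, 1e-4), 1e6)
  Sig_half <- ei$vectors %*% diag(1 / sqrt(lam))
  n0 <- max(10 * K, 3 * d)
  archive <- matrix(rep(o$par, each = n0), n0, d) +
    matrix(rnorm(n0 * d), n0, d) %*% t(Sig_half)
  scales <- pmin(sqrt(rowSums(Sig_half^2)), m$scales * 4)
  start <- o$par
  Hfl <- ei$vectors %*% (t(ei$vectors) * lam)
  indep <- list(m = o$par, H = Hfl, blocks = m$refresh_blocks, adapt = TRUE)
  init <- matrix(rep(start, each = K), K, d) +
    matrix(rnorm(K * d, 0, 0.1), K, d) * rep(scales, each = K)
  # keep the first chain at the mode
  init[1, ] <- start
  run <- demcz(m$logpost, init, scales, sampler, seed = seed,
               gibbs_blocks = m$gibbs_blocks, archive = archive,
               indep = indep, recenter = m$recenter,
               extra_moves = m$extra_moves)
  dimnames(run$draws) <- list(NULL, NULL, m$par_names)

  fit <- structure(list(
    model = model, family = m$family, draws = run$draws,
    accept_rate = run$accept_rate, sampler = sampler, seed = seed,
    par_names = m$par_names, report_idx = m$report_idx, idx = m$idx,
    cells = m[intersect(c("cells", "cells_vz", "cells_at"), names(m))],
    X = m[intersect(c("X", "Xvz", "Xat"), names(m))],
    subjects = m$subjects, n_trials = m$n_trials, table = m$table),
    class = "amyg_fit")
  fit$convergence <- diagnostics(run$draws[, , m$report_idx, drop = FALSE],
                                 rhat_max = sampler$rhat_max,
                                 ess_min = sampler$ess_min)
  if (sampler$check && !all(fit$convergence$pass)) {
    bad <- fit$convergence[!fit$convergence$pass, ]
    stop(structure(class = c("amyg_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "convergence failure in %d parameter(s); worst R-hat %.3f, min ESS %.0f",
                     nrow(bad), max(bad$rhat), min(bad$ess)),
                     call = sys.call(-1), fit = fit)))
  }
  fit
}

# Flatten draws to a (n_draws x d) matrix.
draw_matrix <- function(fit) {
  dm <- fit$draws
  matrix(aperm(dm, c(1, 2, 3)), dim(dm)[1] * dim(dm)[2], dim(dm)[3],
         dimnames = list(NULL, dimnames(dm)[[3]]))
}

# Per-draw cell values of a model parameter on its response (native) scale.
# Returns a draws x cells matrix plus the cell data.frame.
cell_draws <- function(fit, parameter) {
  dm <- draw_matrix(fit)
  if (fit$model == "latency") {
    stopifnot(parameter %in% c("mu", "latency"))
    beta <- dm[, fit$idx$beta, drop = FALSE]
    mu <- beta %*% t(fit$X$X)
    if (parameter == "mu") return(list(values = mu, cells = fit$cells$cells))
    sigma <- exp(dm[, fit$idx$ls])
    delta <- exp(dm[, fit$idx$ld])
    # expected latency at the typical subject (random intercepts at zero)
    list(values = delta + exp(mu + sigma^2 / 2), cells = fit$cells$cells)
  } else if (fit$model == "choice") {
    stopifnot(parameter %in% c("theta"))
    eta <- dm[, fit$idx$beta, drop = FALSE] %*% t(fit$X$X)
    list(values = plogis(eta), cells = fit$cells$cells)
  } else {
    stopifnot(parameter %in% c("v", "z", "a", "t0"))
    if (parameter %in% c("v", "z")) {
      b <- dm[, fit$idx[[paste0("beta_", substr(parameter, 1, 1))]], drop = FALSE]
      val <- b %*% t(fit$X$Xvz)
      if (parameter == "z") val <- plogis(val)
      list(values = val, cells = fit$cells$cells_vz)
    } else {
      b <- dm[, fit$idx[[if (parameter == "a") "beta_a" else "beta_t"]],
              drop = FALSE]
      val <- exp(b %*% t(fit$X$Xat))
      if (parameter == "t0") val <- val * 1000 # report in ms
      list(values = val, cells = fit$cells$cells_at)
    }
  }
}

#' Posterior contrast from a fitted model
#'
#' Applies a weight vector over the model's factorial cells to the per-draw
#' response-scale cell values and summarizes the resulting scalar posterior:
#' mean, 95% credible interval (2.5/97.5 percentiles) and `P(effect)`, the
#' posterior mass on the side of zero of the estimated direction. Confound
#' factors (hemifield of presentation in the latency and choice models) are
#' marginalized by equal-weight averaging: they never enter the cells, and a
#' contrast referencing them is refused.
#'
#' @param fit an `amyg_fit`.
#' @param parameter model parameter: `"latency"` (expected latency, ms) or
#'   `"mu"` for the latency model; `"theta"` for choice; `"v"`, `"z"`,
#'   `"a"`, `"t0"` for the drift-diffusion model.
#' @param weights numeric weight vector over that parameter's cells (see
#'   `fit$cells`), or the name of a planned contrast.
#' @return A one-row data.frame: `mean`, `ci_low`, `ci_high`, `p_effect`,
#'   `scale`.
#' @export
contrast <- function(fit, parameter, weights) {
  stopifnot(inherits(fit, "amyg_fit"))
  if (is.character(parameter) && parameter %in% c("hemifield", "hemi"))
    stop("hemifield is a confound: it is marginalized out and cannot be contrasted")
  cd <- cell_draws(fit, parameter)
  if (is.character(weights)) {
    defs <- planned_defs(fit, parameter)
    if (!weights %in% names(defs)) stop("unknown planned contrast: ", weights)
    weights <- defs[[weights]]
  }
  stopifnot(length(weights) == ncol(cd$values))
  x <- drop(cd$values %*% weights)
  summarize_contrast(x, scale_label(fit$model, parameter))
}

summarize_contrast <- function(x, scale = "") {
  ci <- unname(quantile(x, c(0.025, 0.975), type = 7))
  p_pos <- mean(x > 0); p_neg <- mean(x < 0)
  data.frame(mean = mean(x), ci_low = ci[1], ci_high = ci[2],
             p_effect = max(p_pos, p_neg), scale = scale,
             stringsAsFactors = FALSE)
}

scale_label <- function(model, parameter) {
  switch(parameter,
         latency = "ms (response scale)", mu = "log-ms (link scale)",
         theta = "rate", z = "start point (native)", v = "evidence/s",
         a = "boundary separation", t0 = "ms", parameter)
}

planned_defs <- function(fit, parameter) {
  if (fit$model %in% c("latency", "choice")) {
    f3 <- if (fit$model == "latency") c("emotion", "fear") else c("latbin", "Early")
    contrast_defs_behaviour(fit$cells$cells, f3[1], f3[2])
  } else if (parameter %in% c("v", "z")) {
    contrast_defs_vz(fit$cells$cells_vz)
  } else {
    contrast_defs_at(fit$cells$cells_at)
  }
}

#' The planned posterior contrasts for one fitted model
#'
#' Emits the pre-planned contrast suite of the fitted family, each summarized
#' on its reporting scale (latency in ms via posterior differencing of
#' expected latencies at the typical subject; choice as rate differences;
#' drift-diffusion parameters on their native scales, `t0` in ms):
#'
#' * latency / choice: main effect of Disruption presence; Disruption
#'   laterality (Contra - Ipsi) within Yield; laterality x Emotion (resp. x
#'   Latency bin) within Yield; the Instruction x laterality x Emotion
#'   (resp. Latency) three-way pattern difference; and the third factor's
#'   main effect.
#' * ddm: laterality within Yield and Instruction x laterality for `v` and
#'   `z`; Instruction, Disruption presence and their interaction for `a`
#'   and `t0`.
#'
#' @param fit an `amyg_fit`.
#' @return A data.frame with one row per planned contrast.
#' @export
planned_contrasts <- function(fit) {
  stopifnot(inherits(fit, "amyg_fit"))
  rows <- list()
  if (fit$model %in% c("latency", "choice")) {
    parameter <- if (fit$model == "latency") "latency" else "theta"
    defs <- planned_defs(fit, parameter)
    for (nm in names(defs))
      rows[[nm]] <- cbind(contrast = nm, parameter = parameter,
                          contrast(fit, parameter, defs[[nm]]))
  } else {
    for (parameter in c("z", "v")) {
      defs <- planned_defs(fit, parameter)
      for (nm in names(defs))
        rows[[paste(parameter, nm, sep = "_")]] <-
          cbind(contrast = paste(parameter, nm, sep = "_"),
                parameter = parameter, contrast(fit, parameter, defs[[nm]]))
    }
    for (parameter in c("a", "t0")) {
      defs <- planned_defs(fit, parameter)
      for (nm in names(defs))
        rows[[paste(parameter, nm, sep = "_")]] <-
          cbind(contrast = paste(parameter, nm, sep = "_"),
                parameter = parameter, contrast(fit, parameter, defs[[nm]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
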