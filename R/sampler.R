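#' Sampler options for the hierarchical model fits
#'
#' Posteriors are sampled with differential-evolution MCMC with a historical
#' archive (DE-MCz), a gradient-free multiple-chain scheme whose proposals
#' are scaled difference vectors of past states. It self-adapts to the
#' posterior's correlation structure, which suits the strongly correlated
#' hierarchical drift-diffusion posterior, at the cost of needing more
#' iterations than gradient-based samplers; the convergence gate below
#' enforces the same split R-hat / effective-sample-size standards.
#'
#' @param chains number of parallel chains (>= 4 recommended).
#' @param iter total iterations per chain, including burn-in.
#' @param burn burn-in iterations discarded per chain.
#' @param thin keep every `thin`-th post-burn-in state.
#' @param jitter_sd SD of the small Normal jitter added to every proposal,
#'   relative to each parameter's initialization scale.
#' @param archive_thin archive the chain states every this many iterations.
#' @param check if TRUE, [fit_behaviour()] raises a convergence error when
#'   any reported parameter has split R-hat above `rhat_max` or bulk ESS
#'   below `ess_min`.
#' @param rhat_max,ess_min convergence thresholds (defaults 1.01 / 400).
#' @return A list of class `sampler_options`.
#' @export
sampler_options <- function(chains = 6, iter = 4000, burn = 1500, thin = 5,
                            jitter_sd = 1e-4, archive_thin = 5,
                            check = TRUE, rhat_max = 1.01, ess_min = 400) {
  stopifnot(chains >= 2, iter > burn, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), thin = as.integer(thin),
                 jitter_sd = jitter_sd, archive_thin = as.integer(archive_thin),
                 check = isTRUE(check), rhat_max = rhat_max, ess_min = ess_min),
            class = "sampler_options")
}

# Exact conditional draw of a random-intercept log-SD given the centered
# deviations u: p(sd | u) ~ prod N(u; 0, sd) x half-Normal(sd; 0, hyper),
# sampled on a log-SD grid (griddy Gibbs). Data-free, so no likelihood call.
draw_lsd <- function(u, sd_hyper, grid = seq(-8, 2.5, length.out = 301)) {
  K <- sum(u^2); S <- length(u)
  logw <- -0.5 * K * exp(-2 * grid) - S * grid -
    0.5 * exp(2 * grid) / sd_hyper^2 + grid
  w <- exp(logw - max(logw))
  g <- sample.int(length(grid), 1L, prob = w)
  grid[g] + runif(1, -0.5, 0.5) * (grid[2] - grid[1])
}

# DE-MCz: ter Braak & Vrugt (2008). `logpost` maps a K x d matrix of
# parameter vectors to a length-K vector of log posterior densities.
# `init` is the chain start matrix (chains x d); `scales` the per-parameter
# initialization scale used to seed the archive and size the jitter.
# `gibbs_blocks` lists (lsd index, u indices) pairs for which the SD
# hyperparameter is refreshed by the exact conditional every
# `gibbs_every` iterations.
# `indep`, if given, enables independence proposals from a multivariate-t
# approximation (list: m = centre, L = scale square root, H = precision,
# df): accepted moves are full posterior refreshes, which breaks the slow
# random walk along strongly correlated ridges.
# `recenter` lists (int = intercept index, u = deviation indices,
# lsd = log-SD index) triples: the move shifts the intercept by eps and all
# deviations by -eps, which leaves the likelihood invariant (the ridge the
# centered parameterization creates) and is accepted on the prior ratio.
# `extra_moves` is a list of model-specific move functions f(x, lp, logpost)
# returning list(x, lp); each must be a valid MH kernel on its own.
demcz <- function(logpost, init, scales, opts, seed = 1L,
                  gibbs_blocks = NULL, sd_hyper = 1, archive = NULL,
                  indep = NULL, recenter = NULL, extra_moves = NULL) {
  set.seed(seed)
  K <- nrow(init); d <- ncol(init)
  n_keep <- floor((opts$iter - opts$burn) / opts$thin)
  draws <- array(NA_real_, c(n_keep, K, d))

  # seed the archive around the start with per-parameter dispersion, unless
  # a caller-provided archive (e.g. a Laplace approximation) is given
  if (is.null(archive)) {
    n0 <- max(10 * K, 2 * d)
    Z <- init[rep_len(seq_len(K), n0), , drop = FALSE] +
      matrix(rnorm(n0 * d), n0, d) * rep(scales, each = n0)
  } else {
    Z <- archive
  }
  nz <- nrow(Z)

  x <- init
  lp <- logpost(x)
  if (all(!is.finite(lp))) stop("sampler initialization has zero posterior mass")
  # nudge any chain stuck at -Inf onto the best start
  bad <- !is.finite(lp)
  if (any(bad)) { x[bad, ] <- x[rep(which.max(lp), sum(bad)), ]; lp[bad] <- max(lp) }

  # Block-conditional refresh move: propose the `indep$b` coordinate block
  # from its conditional under the Laplace approximation (Gaussian with the
  # mode's precision), holding the remaining coordinates fixed, with the
  # usual MH correction. The fixed-effect block is close to Gaussian given
  # the rest, so these proposals accept often and act as near-independent
  # refreshes of exactly the reported parameters.
  if (!is.null(indep)) {
    make_blocks <- function(H, m) {
      lapply(indep$blocks, function(b) {
        cidx <- setdiff(seq_len(d), b)
        Hbb <- H[b, b, drop = FALSE]
        list(b = b, cidx = cidx, Hbb = Hbb,
             Hbc = H[b, cidx, drop = FALSE], Ub = chol(Hbb), m = m)
      })
    }
    blocks <- make_blocks(indep$H, indep$m)
    cond_mean <- function(bl, mat) {
      devc <- mat[, bl$cidx, drop = FALSE] -
        rep(bl$m[bl$cidx], each = nrow(mat))
      rep(bl$m[bl$b], each = nrow(mat)) -
        t(backsolve(bl$Ub, backsolve(bl$Ub, bl$Hbc %*% t(devc),
                                     transpose = TRUE)))
    }
    logq_b <- function(bl, mat, cm) {
      dev <- mat[, bl$b, drop = FALSE] - cm
      -0.5 * rowSums((dev %*% bl$Hbb) * dev)
    }
  }

  gamma0 <- 2.38 / sqrt(2 * d)
  acc <- 0; tot <- 0; ki <- 0; acc_i <- 0; tot_i <- 0
  for (it in seq_len(opts$iter)) {
    # adapt the refresh-block Gaussian to the sampled posterior while still
    # in burn-in (the kernel is frozen before any retained draw)
    if (!is.null(indep) && isTRUE(indep$adapt) &&
        (it == floor(0.6 * opts$burn) || it == opts$burn - 1)) {
      recent <- Z[max(1, nz - 1500):nz, , drop = FALSE]
      # inflate the empirical covariance: a burn-in archive underestimates
      # the posterior spread, and too-tight conditionals freeze the chains
      C <- stats::cov(recent) * 1.5
      C <- C + diag(d) * max(diag(C)) * 1e-6
      Hn <- tryCatch(chol2inv(chol(C)), error = function(e) NULL)
      if (!is.null(Hn))
        blocks <- tryCatch(make_blocks((Hn + t(Hn)) / 2, colMeans(recent)),
                           error = function(e) blocks)
    }
    if (!is.null(indep) && runif(1) < 0.3) {
      bl <- blocks[[sample.int(length(blocks), 1)]]
      cm <- cond_mean(bl, x)
      prop <- x
      prop[, bl$b] <- cm +
        t(backsolve(bl$Ub, t(matrix(rnorm(K * length(bl$b)), K))))
      lp_prop <- logpost(prop)
      accept <- log(runif(K)) <
        lp_prop - lp + logq_b(bl, x, cm) - logq_b(bl, prop, cm)
      accept[!is.finite(lp_prop)] <- FALSE
      x[accept, ] <- prop[accept, , drop = FALSE]
      lp[accept] <- lp_prop[accept]
      acc <- acc + sum(accept); tot <- tot + K
      acc_i <- acc_i + sum(accept); tot_i <- tot_i + K
    } else {
    gamma <- if (runif(1) < 0.1) 1 else gamma0
    r1 <- sample.int(nz, K, replace = TRUE)
    r2 <- sample.int(nz, K, replace = TRUE)
    same <- r1 == r2
    while (any(same)) { r2[same] <- sample.int(nz, sum(same), replace = TRUE)
                        same <- r1 == r2 }
    prop <- x + gamma * (Z[r1, , drop = FALSE] - Z[r2, , drop = FALSE]) +
      matrix(rnorm(K * d), K, d) * rep(opts$jitter_sd * scales, each = K)
    lp_prop <- logpost(prop)
    accept <- log(runif(K)) < lp_prop - lp
    accept[!is.finite(lp_prop)] <- FALSE
    x[accept, ] <- prop[accept, , drop = FALSE]
    lp[accept] <- lp_prop[accept]
    acc <- acc + sum(accept); tot <- tot + K
    }

    if (!is.null(recenter) && it %% 2 == 0) {
      rc <- recenter[[sample.int(length(recenter), 1)]]
      tau <- exp(x[, rc$lsd]) / sqrt(length(rc$u)) + 0.01
      eps <- rnorm(K, 0, tau)
      prop <- x
      prop[, rc$int] <- prop[, rc$int] + eps
      prop[, rc$u] <- prop[, rc$u] - eps
      lp_prop <- logpost(prop)
      accept <- log(runif(K)) < lp_prop - lp # symmetric proposal in eps
      accept[!is.finite(lp_prop)] <- FALSE
      x[accept, ] <- prop[accept, , drop = FALSE]
      lp[accept] <- lp_prop[accept]
    }

    if (!is.null(extra_moves) && it %% 2 == 0) {
      mv <- extra_moves[[sample.int(length(extra_moves), 1)]]
      upd <- mv(x, lp, logpost)
      x <- upd$x; lp <- upd$lp
    }

    if (!is.null(gibbs_blocks) && it %% 5 == 0) {
      for (bl in gibbs_blocks) {
        for (k in seq_len(K)) x[k, bl$lsd] <- draw_lsd(x[k, bl$u], sd_hyper)
      }
      lp <- logpost(x)
    }

    if (it %% opts$archive_thin == 0) { Z <- rbind(Z, x); nz <- nrow(Z) }
    if (it > opts$burn && (it - opts$burn) %% opts$thin == 0) {
      ki <- ki + 1
      if (ki <= n_keep) draws[ki, , ] <- x
    }
  }
  list(draws = draws, accept_rate = acc / tot,
       accept_rate_indep = if (tot_i > 0) acc_i / tot_i else NA_real_,
       logpost_last = lp)
}

# Split R-hat (Gelman et al.): each chain halved, potential scale reduction
# across the 2K half-chains.
split_rhat <- function(mat) {
  # mat: iterations x chains
  n <- nrow(mat); K <- ncol(mat)
  h <- floor(n / 2)
  halves <- cbind(mat[seq_len(h), , drop = FALSE],
                  mat[(n - h + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- h * var(means)
  if (W <= 0) return(if (var(means) > 0) Inf else 1)
  sqrt(((h - 1) / h * W + B / h) / W)
}

# Bulk effective sample size from chain-averaged autocovariances with
# Geyer's initial-positive-sequence truncation.
ess_bulk <- function(mat) {
  n <- nrow(mat); K <- ncol(mat)
  if (n < 4) return(NA_real_)
  ac <- sapply(seq_len(K), function(k) {
    v <- mat[, k] - mean(mat[, k])
    a <- stats::acf(v, lag.max = min(n - 2, 500), plot = FALSE,
                    demean = FALSE, type = "covariance")$acf[, 1, 1]
    a
  })
  W <- mean(apply(mat, 2, var))
  B <- n * var(colMeans(mat))
  var_plus <- W * (n - 1) / n + B / n
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (W - rowMeans(ac)) / var_plus # lag 0, 1, 2, ...
  rho[1] <- 1
  # Geyer pairs
  maxp <- floor((length(rho) - 1) / 2)
  tau <- 1
  prev <- Inf
  for (p in seq_len(maxp)) {
    pair <- rho[2 * p] + rho[2 * p + 1]
    if (pair < 0) break
    pair <- min(pair, prev) # enforce monotone decrease
    tau <- tau + 2 * pair
    prev <- pair
  }
  K * n / tau
}

#' Convergence diagnostics for posterior draws
#'
#' Per-parameter split R-hat and bulk effective sample size, with pass/fail
#' against the configured thresholds.
#'
#' @param draws a 3-d array (iterations x chains x parameters) with parameter
#'   names in `dimnames[[3]]`, or a fitted model object.
#' @param rhat_max,ess_min thresholds used for the pass/fail flags.
#' @return A data.frame (class `convergence_report`) with one row per
#'   parameter: `rhat`, `ess`, `pass`.
#' @export
diagnostics <- function(draws, rhat_max = 1.01, ess_min = 400) {
  if (inherits(draws, "amyg_fit")) draws <- draws$draws
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[2] < 2) stop("diagnostics require at least two chains")
  pn <- dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  out <- data.frame(
    parameter = pn,
    rhat = vapply(seq_len(dim(draws)[3]),
                  function(j) split_rhat(draws[, , j]), numeric(1)),
    ess = vapply(seq_len(dim(draws)[3]),
                 function(j) ess_bulk(draws[, , j]), numeric(1)),
    stringsAsFactors = FALSE)
  out$pass <- is.finite(out$rhat) & out$rhat <= rhat_max & out$ess >= ess_min
  class(out) <- c("convergence_report", "data.frame")
  attr(out, "thresholds") <- c(rhat_max = rhat_max, ess_min = ess_min)
  out
}

#' @export
print.convergence_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("Convergence: %d/%d parameters pass (R-hat <= %.3f, ESS >= %g)\n",
              sum(x$pass), nrow(x), th["rhat_max"], th["ess_min"]))
  worst <- x[order(-x$rhat), ][seq_len(min(5, nrow(x))), ]
  cat("worst R-hat:\n")
  print.data.frame(worst, row.names = FALSE, digits = 4)
  invisible(x)
}
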