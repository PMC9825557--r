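#' @export
print.amyg_fit <- function(x, ...) {
  fam <- c(latency = "shifted-lognormal latency",
           choice = "Bernoulli choice",
           ddm = "hierarchical drift-diffusion")[x$model]
  dm <- dim(x$draws)
  cat(sprintf("%s model: %d trials, %d participants\n", fam, x$n_trials,
              length(x$subjects)))
  cat(sprintf("  draws: %d iterations x %d chains (%d parameters), acceptance %.2f\n",
              dm[1], dm[2], dm[3], x$accept_rate))
  cv <- x$convergence
  cat(sprintf("  convergence: max R-hat %.3f, min ESS %.0f (%s)\n",
              max(cv$rhat), min(cv$ess),
              if (all(cv$pass)) "pass" else "FAIL"))
  invisible(x)
}

#' @export
summary.amyg_fit <- function(object, ...) {
  dm <- draw_matrix(object)
  idx <- object$report_idx
  cv <- object$convergence
  tab <- data.frame(
    parameter = object$par_names[idx],
    mean = colMeans(dm[, idx, drop = FALSE]),
    sd = apply(dm[, idx, drop = FALSE], 2, sd),
    ci_low = apply(dm[, idx, drop = FALSE], 2, quantile, 0.025),
    ci_high = apply(dm[, idx, drop = FALSE], 2, quantile, 0.975),
    rhat = cv$rhat, ess = cv$ess, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(model = object$model, fixed = tab,
                 n_trials = object$n_trials,
                 n_subjects = length(object$subjects)),
            class = "summary.amyg_fit")
}

#' @export
print.summary.amyg_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (%s model; %d trials, %d participants)\n",
              x$model, x$n_trials, x$n_subjects))
  print.data.frame(x$fixed, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.amyg_fit <- function(object, ...) {
  dm <- draw_matrix(object)
  setNames(colMeans(dm[, object$report_idx, drop = FALSE]),
           object$par_names[object$report_idx])
}

#' Trace and density plots for a fitted model
#'
#' Plots sampling traces (one line per chain) and posterior densities for
#' the requested parameters, by default the four fixed effects with the
#' largest split R-hat.
#'
#' @param x an `amyg_fit`.
#' @param pars parameter names (see `x$par_names`); default picks the worst
#'   mixers among reported parameters.
#' @param ... unused.
#' @export
plot.amyg_fit <- function(x, pars = NULL, ...) {
  cv <- x$convergence
  if (is.null(pars))
    pars <- cv$parameter[order(-cv$rhat)][seq_len(min(4, nrow(cv)))]
  j <- match(pars, x$par_names)
  if (anyNA(j)) stop("unknown parameter name(s)")
  old <- par(mfrow = c(length(j), 2), mar = c(3, 4, 1.5, 1))
  on.exit(par(old))
  for (k in seq_along(j)) {
    tr <- x$draws[, , j[k]]
    matplot(tr, type = "l", lty = 1, xlab = "", ylab = pars[k],
            main = if (k == 1) "trace" else "")
    dens <- stats::density(as.vector(tr))
    plot(dens, main = if (k == 1) "posterior" else "", xlab = "")
    abline(v = mean(tr), lty = 2)
  }
  invisible(x)
}

#' Posterior predictive simulation from a fitted model
#'
#' Draws `nsim` parameter vectors from the posterior and regenerates the
#' fitted trials from each, returning replicated trial tables. Latency-model
#' replicates redraw latencies (and carry the observed emotion labels);
#' choice-model replicates redraw choices; drift-diffusion replicates redraw
#' both choice and latency from the Wiener likelihood.
#'
#' @param object an `amyg_fit`.
#' @param nsim number of replicated tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` data.frames shaped like the fitted table.
#' @export
simulate.amyg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dm <- draw_matrix(object)
  tab <- object$table
  S <- length(object$subjects)
  si <- match(tab$participant, object$subjects)
  picks <- sample.int(nrow(dm), nsim, replace = TRUE)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    par <- dm[picks[r], ]
    rep_tab <- tab
    if (object$model == "latency") {
      mu_cells <- drop(object$X$X %*% par[object$idx$beta])
      ci <- cell_index(tab[c("instruction", "disruption", "emotion")],
                       object$cells$cells)
      u_m <- par[grep("^u_mu\\[", object$par_names)]
      u_s <- par[grep("^u_lsigma\\[", object$par_names)]
      u_d <- par[grep("^u_ldelta\\[", object$par_names)]
      mu_i <- mu_cells[ci] + par[object$idx$bh] * tab$hemi_x + u_m[si]
      sig <- exp(par[object$idx$ls] + u_s)[si]
      del <- exp(par[object$idx$ld] + u_d)[si]
      rep_tab$latency_ms <- del + rlnorm(nrow(tab), mu_i, sig)
    } else if (object$model == "choice") {
      lp <- drop(object$X$X %*% par[object$idx$beta])
      ci <- cell_index(tab[c("instruction", "disruption", "latbin")],
                       object$cells$cells)
      u_t <- par[grep("^u_theta\\[", object$par_names)]
      th <- plogis(lp[ci] + par[object$idx$bh] * tab$hemi_x + u_t[si])
      rep_tab$choice <- ifelse(runif(nrow(tab)) < th, "fear", "neutral")
    } else {
      cvz <- drop(object$X$Xvz %*% par[object$idx$beta_v])
      czz <- drop(object$X$Xvz %*% par[object$idx$beta_z])
      caa <- drop(object$X$Xat %*% par[object$idx$beta_a])
      ctt <- drop(object$X$Xat %*% par[object$idx$beta_t])
      ivz <- cell_index(data.frame(instruction = tab$instruction,
                                   disruption = tab$disruption,
                                   hemifield = tab$hemifield_fear),
                        object$cells$cells_vz[c("instruction", "disruption",
                                                "hemifield")])
      iat <- cell_index(data.frame(instruction = tab$instruction,
                                   presence = ifelse(tab$disruption == "None",
                                                     "None", "Present")),
                        object$cells$cells_at)
      ev <- par[grep("^u_v\\[", object$par_names)]
      ez <- par[grep("^u_z\\[", object$par_names)]
      ea <- par[grep("^u_a\\[", object$par_names)]
      et <- par[grep("^u_t0\\[", object$par_names)]
      key <- paste(si, ivz, iat)
      for (k in unique(key)) {
        rows <- which(key == k)
        s <- si[rows[1]]
        v <- cvz[ivz[rows[1]]] + ev[s]
        z <- plogis(czz[ivz[rows[1]]] + ez[s])
        a <- exp(caa[iat[rows[1]]] + ea[s])
        t0 <- exp(ctt[iat[rows[1]]] + et[s])
        sim <- sim_ddm_hybrid_cpp(length(rows), v, a, z, t0, 2.5e-4)
        rep_tab$choice[rows] <- ifelse(sim$upper == 1, "fear", "neutral")
        rep_tab$latency_ms[rows] <- sim$rt * 1000
      }
    }
    out[[r]] <- rep_tab
  }
  out
}

#' Posterior expected response by factorial cell
#'
#' Posterior mean and credible interval of the response-scale quantity in
#' each factorial cell: expected latency (ms) for the latency model,
#' fear-choice rate for the choice model, and each Wiener parameter's native
#' value for the drift-diffusion model.
#'
#' @param object an `amyg_fit`.
#' @param parameter which parameter to tabulate (defaults to the family's
#'   response parameter; for `"ddm"` one of `"v"`, `"z"`, `"a"`, `"t0"`).
#' @param ... unused.
#' @return The cell table with posterior `mean`, `ci_low`, `ci_high`.
#' @export
predict.amyg_fit <- function(object, parameter = NULL, ...) {
  if (is.null(parameter))
    parameter <- switch(object$model, latency = "latency", choice = "theta",
                        ddm = "z")
  cd <- cell_draws(object, parameter)
  cells <- cd$cells[!grepl("^(v|z|a|t0|mu|logit|log|theta|expected)",
                           names(cd$cells))]
  cells$mean <- colMeans(cd$values)
  cells$ci_low <- apply(cd$values, 2, quantile, 0.025)
  cells$ci_high <- apply(cd$values, 2, quantile, 0.975)
  cells
}
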