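# Model internals: data preparation, parameter layouts and log posteriors for
# the three hierarchical families. All factors are sum-to-zero coded, so
# "marginalizing out" a factor is equal-weight averaging over its levels and
# main effects stay interpretable under the imbalanced clinical design.

f_lvl <- list(instruction = c("Yield", "Oppose"),
              disruption = c("None", "Ipsi", "Contra"),
              emotion = c("fear", "neutral"),
              latbin = c("Early", "Late"),
              presence = c("None", "Present"),
              hemifield = c("L", "R"))

# Sum-coded full-factorial design matrix over a cell table.
cells_design <- function(cells) {
  fac <- cells
  for (nm in names(fac)) fac[[nm]] <- factor(fac[[nm]], levels = f_lvl[[nm]])
  form <- stats::as.formula(paste("~", paste(names(fac), collapse = "*")))
  contr <- setNames(rep(list("contr.sum"), ncol(fac)), names(fac))
  X <- stats::model.matrix(form, data = fac, contrasts.arg = contr)
  attr(X, "assign") <- NULL
  X
}

prep_table <- function(table) {
  tab <- table[table$qc == "valid" & !is.na(table$latency_ms), , drop = FALSE]
  if (!nrow(tab)) stop("no valid trials to fit")
  if (is.null(tab$emotion)) tab$emotion <- tab$choice
  tab$hemi_x <- (tab$hemifield_fear == "R") - 0.5
  tab
}

# ---------------------------------------------------------------- latency --

build_latency_model <- function(table, priors = list()) {
  tab <- prep_table(table)
  cells <- cells_behaviour(f_lvl$emotion, "emotion")
  X <- cells_design(cells[c("instruction", "disruption", "emotion")])
  ci <- cell_index(tab[c("instruction", "disruption", "emotion")], cells)
  subjects <- sort(unique(tab$participant))
  S <- length(subjects)
  si <- match(tab$participant, subjects)
  y <- tab$latency_ms
  min_y <- tapply(y, si, min)[as.character(seq_len(S))]

  pr <- utils::modifyList(list(mu_intercept = c(log(250), 1), beta_sd = 1,
                               lsigma0 = c(log(0.3), 1),
                               ldelta0 = c(log(100), 1), sd_hyper = 1), priors)
  p <- ncol(X)
  par_names <- c(paste0("mu_", colnames(X)), "mu_hemifield",
                 "log_sigma0", "log_delta0",
                 paste0("u_mu[", seq_len(S), "]"),
                 paste0("u_lsigma[", seq_len(S), "]"),
                 paste0("u_ldelta[", seq_len(S), "]"),
                 c("lsd_mu", "lsd_lsigma", "lsd_ldelta"))
  d <- length(par_names)
  i_beta <- seq_len(p); i_bh <- p + 1L; i_ls <- p + 2L; i_ld <- p + 3L
  i_em <- p + 3L + seq_len(S); i_es <- p + 3L + S + seq_len(S)
  i_ed <- p + 3L + 2L * S + seq_len(S); i_lsd <- p + 3L + 3L * S + 1:3

  hemi <- tab$hemi_x
  logpost <- function(theta) {
    apply(theta, 1, function(par) {
      lsd <- par[i_lsd]
      if (any(lsd > 5 | lsd < -12)) return(-Inf)
      sds <- exp(lsd)
      beta <- par[i_beta]
      mu_cells <- drop(X %*% beta)
      # centered subject deviations: u ~ N(0, sd) on each link scale
      sigma_s <- exp(par[i_ls] + par[i_es])
      delta_s <- exp(par[i_ld] + par[i_ed])
      if (any(delta_s >= 0.95 * min_y)) return(-Inf)
      mu_i <- mu_cells[ci] + par[i_bh] * hemi + par[i_em][si]
      resid <- y - delta_s[si]
      ll <- sum(stats::dlnorm(resid, mu_i, sigma_s[si], log = TRUE))
      if (!is.finite(ll)) return(-Inf)
      lp_prior <-
        dnorm(beta[1], pr$mu_intercept[1], pr$mu_intercept[2], log = TRUE) +
        sum(dnorm(beta[-1], 0, pr$beta_sd, log = TRUE)) +
        dnorm(par[i_bh], 0, pr$beta_sd, log = TRUE) +
        dnorm(par[i_ls], pr$lsigma0[1], pr$lsigma0[2], log = TRUE) +
        dnorm(par[i_ld], pr$ldelta0[1], pr$ldelta0[2], log = TRUE) +
        sum(dnorm(par[i_em], 0, sds[1], log = TRUE)) +
        sum(dnorm(par[i_es], 0, sds[2], log = TRUE)) +
        sum(dnorm(par[i_ed], 0, sds[3], log = TRUE)) +
        sum(dnorm(sds, 0, pr$sd_hyper, log = TRUE) + lsd + log(2))
      ll + lp_prior
    })
  }

  delta_init <- 0.7 * min(y)
  lr <- log(pmax(y - delta_init, 1))
  mu_emp <- rep(mean(lr), nrow(cells))
  agg <- tapply(lr, ci, mean)
  mu_emp[as.integer(names(agg))] <- agg
  init <- numeric(d)
  init[i_beta] <- solve(X, mu_emp)
  init[i_ls] <- log(max(sd(lr), 0.05))
  init[i_ld] <- log(delta_init)
  init[i_lsd] <- log(0.1)
  scales <- rep(0.05, d)
  scales[c(i_em, i_es, i_ed)] <- 0.1
  scales[i_lsd] <- 0.5
  scales[c(i_ls, i_ld)] <- 0.1

  # Exact conjugate Gibbs draw of the jointly-Gaussian block (cell betas,
  # hemifield slope, subject intercepts) given sigma, delta and the
  # intercept SD: the log-residual regression is an ordinary Gaussian
  # linear model, so the conditional is sampled directly.
  S_ind <- matrix(0, length(y), S)
  S_ind[cbind(seq_along(y), si)] <- 1
  bigW <- cbind(X[ci, , drop = FALSE], hemi, S_ind)
  nW <- ncol(bigW)
  p0m <- c(pr$mu_intercept[1] / pr$mu_intercept[2]^2, rep(0, nW - 1))
  conj_move <- function(x, lp, logpost) {
    K <- nrow(x)
    for (k in seq_len(K)) {
      par <- x[k, ]
      sig_s <- exp(par[i_ls] + par[i_es])
      del_s <- exp(par[i_ld] + par[i_ed])
      w <- 1 / sig_s[si]^2
      yp <- log(y - del_s[si])
      prec0 <- c(1 / pr$mu_intercept[2]^2,
                 rep(1 / pr$beta_sd^2, p),   # non-intercept betas + hemifield
                 rep(exp(-2 * par[i_lsd[1]]), S))
      A <- crossprod(bigW, bigW * w)
      diag(A) <- diag(A) + prec0
      b <- crossprod(bigW, yp * w) + p0m
      ch <- chol(A)
      mn <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
      x[k, c(i_beta, i_bh, i_em)] <- mn + backsolve(ch, rnorm(nW))
    }
    list(x = x, lp = logpost(x))
  }

  # Per-subject sigma refresh: propose sigma_s^2 from the inverse-gamma
  # that matches the subject's residual likelihood exactly; on the log-SD
  # scale the proposal density is proportional to the likelihood, so the
  # acceptance ratio reduces to the prior ratio of the subject deviation.
  n_s <- tabulate(si, S)
  sigma_move <- function(x, lp, logpost) {
    K <- nrow(x)
    for (k in seq_len(K)) {
      par <- x[k, ]
      del_s <- exp(par[i_ld] + par[i_ed])
      mu_cells <- drop(X %*% par[i_beta])
      mu_i <- mu_cells[ci] + par[i_bh] * hemi + par[i_em][si]
      r2 <- as.numeric(tapply((log(y - del_s[si]) - mu_i)^2, si, sum))
      sig2_new <- 1 / rgamma(S, n_s / 2, r2 / 2)
      u_new <- 0.5 * log(sig2_new) - par[i_ls]
      u_old <- par[i_es]
      sd_ls <- exp(par[i_lsd[2]])
      acc <- log(runif(S)) < dnorm(u_new, 0, sd_ls, log = TRUE) -
        dnorm(u_old, 0, sd_ls, log = TRUE)
      u_old[acc] <- u_new[acc]
      x[k, i_es] <- u_old
    }
    list(x = x, lp = logpost(x))
  }

  # shift-versus-location ridge move: raise delta and lower the lognormal
  # median so the expected latency is nearly unchanged; deterministic map
  # given eps, MH-corrected with its Jacobian
  i_b1 <- i_beta[1]
  tradeoff_move <- function(x, lp, logpost) {
    K <- nrow(x)
    delta <- exp(x[, i_ld]); M <- exp(x[, i_b1])
    eps <- rnorm(K, 0, 10)
    ok <- (delta + eps > 5) & (M - eps > 5)
    prop <- x
    prop[ok, i_ld] <- log(delta[ok] + eps[ok])
    prop[ok, i_b1] <- log(M[ok] - eps[ok])
    lJ <- (x[, i_ld] - prop[, i_ld]) + (x[, i_b1] - prop[, i_b1])
    lp_prop <- logpost(prop)
    accept <- ok & is.finite(lp_prop) & log(runif(K)) < lp_prop - lp + lJ
    x[accept, ] <- prop[accept, , drop = FALSE]
    lp[accept] <- lp_prop[accept]
    list(x = x, lp = lp)
  }

  list(family = "shifted_lognormal", logpost = logpost, init = init,
       scales = scales, par_names = par_names, cells = cells, X = X,
       subjects = subjects, n_trials = nrow(tab), table = tab,
       extra_moves = list(conj_move, tradeoff_move, sigma_move),
       report_idx = c(i_beta, i_bh, i_ls, i_ld),
       refresh_blocks = list(c(i_beta, i_bh, i_ls, i_ld)),
       recenter = list(list(int = i_beta[1], u = i_em, lsd = i_lsd[1]),
                       list(int = i_ls, u = i_es, lsd = i_lsd[2]),
                       list(int = i_ld, u = i_ed, lsd = i_lsd[3])),
       gibbs_blocks = list(list(lsd = i_lsd[1], u = i_em),
                           list(lsd = i_lsd[2], u = i_es),
                           list(lsd = i_lsd[3], u = i_ed)),
       idx = list(beta = i_beta, bh = i_bh, ls = i_ls, ld = i_ld,
                  lsd = i_lsd))
}

# ----------------------------------------------------------------- choice --

build_choice_model <- function(table, priors = list()) {
  tab <- prep_table(table)
  if (is.null(tab$latbin) || anyNA(tab$latbin))
    stop("choice model requires a latbin column; run median_split() first")
  cells <- cells_behaviour(f_lvl$latbin, "latbin")
  X <- cells_design(cells[c("instruction", "disruption", "latbin")])
  ci <- cell_index(tab[c("instruction", "disruption", "latbin")], cells)
  subjects <- sort(unique(tab$participant))
  S <- length(subjects)
  si <- match(tab$participant, subjects)
  y <- as.integer(tab$choice == "fear")

  pr <- utils::modifyList(list(beta_sd = 1, sd_hyper = 1), priors)
  p <- ncol(X)
  par_names <- c(paste0("theta_", colnames(X)), "theta_hemifield",
                 paste0("u_theta[", seq_len(S), "]"), "lsd_theta")
  d <- length(par_names)
  i_beta <- seq_len(p); i_bh <- p + 1L
  i_et <- p + 1L + seq_len(S); i_lsd <- p + 1L + S + 1L

  hemi <- tab$hemi_x
  logpost <- function(theta) {
    apply(theta, 1, function(par) {
      lsd <- par[i_lsd]
      if (lsd > 5 || lsd < -12) return(-Inf)
      sdt <- exp(lsd)
      lp_cells <- drop(X %*% par[i_beta])
      eta <- lp_cells[ci] + par[i_bh] * hemi + par[i_et][si]
      ll <- sum(ifelse(y == 1L, stats::plogis(eta, log.p = TRUE),
                       stats::plogis(-eta, log.p = TRUE)))
      ll +
        sum(dnorm(par[i_beta], 0, pr$beta_sd, log = TRUE)) +
        dnorm(par[i_bh], 0, pr$beta_sd, log = TRUE) +
        sum(dnorm(par[i_et], 0, sdt, log = TRUE)) +
        dnorm(sdt, 0, pr$sd_hyper, log = TRUE) + lsd + log(2)
    })
  }

  emp <- rep(qlogis(pmin(pmax(mean(y), 0.05), 0.95)), nrow(cells))
  agg <- tapply(y, ci, mean)
  emp[as.integer(names(agg))] <- qlogis(pmin(pmax(agg, 0.05), 0.95))
  init <- numeric(d)
  init[i_beta] <- solve(X, emp)
  init[i_lsd] <- log(0.1)
  scales <- rep(0.1, d)
  scales[i_et] <- 0.1
  scales[i_lsd] <- 0.5

  list(family = "bernoulli", logpost = logpost, init = init, scales = scales,
       par_names = par_names, cells = cells, X = X, subjects = subjects,
       n_trials = nrow(tab), table = tab,
       report_idx = c(i_beta, i_bh),
       refresh_blocks = list(c(i_beta, i_bh)),
       recenter = list(list(int = i_beta[1], u = i_et, lsd = i_lsd)),
       gibbs_blocks = list(list(lsd = i_lsd, u = i_et)),
       idx = list(beta = i_beta, bh = i_bh, lsd = i_lsd))
}

# ----------------------------------------------------------------- wiener --

build_wiener_model <- function(table, priors = list()) {
  tab <- prep_table(table)
  cvz <- cells_vz(f_lvl$hemifield)
  cat_ <- cells_at()
  Xvz <- cells_design(cvz[c("instruction", "disruption", "hemifield")])
  Xat <- cells_design(cat_[c("instruction", "presence")])
  ivz <- cell_index(data.frame(instruction = tab$instruction,
                               disruption = tab$disruption,
                               hemifield = tab$hemifield_fear),
                    cvz[c("instruction", "disruption", "hemifield")])
  iat <- cell_index(data.frame(instruction = tab$instruction,
                               presence = ifelse(tab$disruption == "None",
                                                 "None", "Present")),
                    cat_)
  subjects <- sort(unique(tab$participant))
  S <- length(subjects)
  si <- match(tab$participant, subjects)
  rt <- tab$latency_ms / 1000
  # per subject x at-cell minimum RT, the upper bound region for t0
  min_rt <- matrix(Inf, S, nrow(cat_))
  for (s in seq_len(S)) {
    for (cc in unique(iat[si == s])) {
      min_rt[s, cc] <- min(rt[si == s & iat == cc])
    }
  }

  pv <- ncol(Xvz); pa <- ncol(Xat)
  pr <- utils::modifyList(list(beta_sd = 1, t0_intercept = log(0.2),
                               sd_hyper = 1), priors)
  prior_mean <- rep(0, 2 * pv + 2 * pa)
  prior_mean[2 * pv + pa + 1] <- pr$t0_intercept
  prior_sd <- rep(pr$beta_sd, 2 * pv + 2 * pa)

  par_names <- c(paste0("v_", colnames(Xvz)), paste0("z_", colnames(Xvz)),
                 paste0("a_", colnames(Xat)), paste0("t0_", colnames(Xat)),
                 paste0("u_v[", seq_len(S), "]"),
                 paste0("u_z[", seq_len(S), "]"),
                 paste0("u_a[", seq_len(S), "]"),
                 paste0("u_t0[", seq_len(S), "]"),
                 c("lsd_v", "lsd_z", "lsd_a", "lsd_t0"))
  d <- length(par_names)
  nb <- 2 * pv + 2 * pa

  data <- list(rt = rt, upper = as.integer(tab$choice == "fear"),
               subj = si - 1L, cell_vz = ivz - 1L, cell_at = iat - 1L,
               Xvz = Xvz, Xat = Xat, min_rt = min_rt,
               prior_mean = prior_mean, prior_sd = prior_sd,
               sd_hyper = pr$sd_hyper)
  logpost <- function(theta) wiener_logpost_cpp(theta, data)

  # data-informed start: z from cell choice rates (z ~ P(upper) near v = 0),
  # t0 just under each at-cell's fastest response, a from mean decision time
  # under the zero-drift identity E[DT] = a^2 z (1 - z)
  init <- numeric(d)
  p_fear <- rep(mean(data$upper), nrow(cvz))
  agg <- tapply(data$upper, ivz, mean)
  p_fear[as.integer(names(agg))] <- agg
  p_fear <- pmin(pmax(p_fear, 0.1), 0.9)
  init[pv + seq_len(pv)] <- solve(Xvz, qlogis(p_fear))
  t0_cell <- apply(min_rt, 2, min) * 0.85
  init[2 * pv + pa + seq_len(pa)] <- solve(Xat, log(t0_cell))
  dt_cell <- as.numeric(tapply(rt, iat, mean)) - t0_cell
  zbar <- mean(p_fear)
  a_cell <- sqrt(pmax(dt_cell, 0.02) / (zbar * (1 - zbar)))
  init[2 * pv + seq_len(pa)] <- solve(Xat, log(a_cell))
  init[(nb + 4 * S + 1):d] <- log(0.1)                # RI SDs
  scales <- rep(0.05, d)
  scales[(nb + 1):(nb + 4 * S)] <- 0.1
  scales[(nb + 4 * S + 1):d] <- 0.5

  list(family = "wiener", logpost = logpost, init = init, scales = scales,
       par_names = par_names, cells_vz = cvz, cells_at = cat_,
       Xvz = Xvz, Xat = Xat, subjects = subjects, n_trials = nrow(tab),
       table = tab,
       # gate convergence on the parameters the contrasts report (the fixed
       # effects); the v/z random-intercept SDs are weakly identified
       # nuisances with heavy-tailed posteriors and are monitored via the
       # draws but not gated
       report_idx = seq_len(nb),
       refresh_blocks = list(seq_len(pv), pv + seq_len(pv),
                             2 * pv + seq_len(pa), 2 * pv + pa + seq_len(pa),
                             seq_len(nb)),
       recenter = list(
         list(int = 1L, u = nb + seq_len(S), lsd = nb + 4 * S + 1L),
         list(int = pv + 1L, u = nb + S + seq_len(S), lsd = nb + 4 * S + 2L),
         list(int = 2L * pv + 1L, u = nb + 2L * S + seq_len(S),
              lsd = nb + 4 * S + 3L),
         list(int = 2L * pv + pa + 1L, u = nb + 3L * S + seq_len(S),
              lsd = nb + 4 * S + 4L)),
       gibbs_blocks = lapply(1:4, function(j)
         list(lsd = nb + 4 * S + j, u = nb + (j - 1) * S + seq_len(S))),
       idx = list(beta_v = seq_len(pv), beta_z = pv + seq_len(pv),
                  beta_a = 2 * pv + seq_len(pa), beta_t = 2 * pv + pa + seq_len(pa),
                  lsd = (nb + 4 * S + 1):d))
}
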