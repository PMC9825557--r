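#' Ground truth for the synthetic experiment generator
#'
#' Assembles the generating parameters of a synthetic cohort: per-condition
#' drift-diffusion parameters, shifted-lognormal latency parameters, Bernoulli
#' fear-preference rates, subject-level random-intercept scale, the induced
#' gamma burst injected into LFP epochs, and the scleral-region signal of the
#' face difference images. Default effect sizes are the study's headline
#' point estimates (start-point shift -0.104 between disruption lateralities
#' in Yield, +19 ms non-decision time under disruption, +17 ms
#' laterality-by-emotion latency interaction in Yield, 48%/42% fear
#' preference, a ~99 Hz induced burst shortly after face onset); base values
#' are chosen to give realistic saccadic latency distributions (mean ~290 ms,
#' SD ~55 ms). Effects are injected on each parameter's link scale with
#' offsets solved numerically so that the named response-scale contrast equals
#' its target exactly; the implied true values of every planned contrast are
#' stored in `$contrasts` for recovery tests.
#'
#' @param ddm named list overriding drift-diffusion truth: base values
#'   `a0`, `z0`, `t00` (s); either `v0` (one drift everywhere) or the
#'   fear-preference targets `p_fear_yield` / `p_fear_oppose` from which the
#'   per-instruction drift is solved; and effects `dz_lat_yield`,
#'   `dz_instruction_x_lat` (native z scale), `da_instruction` (native),
#'   `dt0_presence` (s).
#' @param latency overrides for the shifted-lognormal truth: `median0` (ms,
#'   `exp(mu0)`), `sigma0` (log scale), `delta0` (ms) and response-scale (ms)
#'   effects `d_presence`, `d_emotion`, `d_lat_yield`, `d_lat_x_emotion_yield`,
#'   `d_threeway`.
#' @param choice overrides for the Bernoulli truth: `theta_yield`,
#'   `theta_oppose`, and rate-scale effects `d_latbin`, `d_lat_x_bin_yield`,
#'   `d_threeway`.
#' @param subject_sd SD of zero-mean Normal subject intercept deviations,
#'   applied on each parameter's link scale.
#' @param lfp_burst list: `freq_hz`, `center_ms`, `sd_ms` (Gaussian envelope),
#'   `amplitude_pct` (% of baseline power at that frequency).
#' @param sclera list: `amplitude` (signal-to-noise of the scleral signal on
#'   early trials) and `weights` (named multiplier per disruption level).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(ddm = list(), latency = list(), choice = list(),
                         subject_sd = 0.1,
                         lfp_burst = list(), sclera = list()) {
  ddm <- utils::modifyList(list(
    v0 = NULL, a0 = 0.65, z0 = 0.5, t00 = 0.150,
    p_fear_yield = 0.48, p_fear_oppose = 0.42,
    dz_lat_yield = -0.104, dz_instruction_x_lat = 0.072,
    da_instruction = 0.194, dt0_presence = 0.019), ddm)
  latency <- utils::modifyList(list(
    median0 = 150, sigma0 = 0.3, delta0 = 100,
    d_presence = 32, d_emotion = -17, d_lat_yield = -1,
    d_lat_x_emotion_yield = 17, d_threeway = -22), latency)
  choice <- utils::modifyList(list(
    theta_yield = 0.48, theta_oppose = 0.42,
    d_latbin = 0.11, d_lat_x_bin_yield = -0.15, d_threeway = 0.16), choice)
  lfp_burst <- utils::modifyList(list(
    freq_hz = 99, center_ms = 80, sd_ms = 25, amplitude_pct = 50), lfp_burst)
  sclera <- utils::modifyList(list(
    amplitude = 1, weights = c(None = 0.7, Ipsi = 1, Contra = 0)), sclera)
  if (subject_sd < 0) stop("subject_sd must be >= 0")

  truth <- structure(list(
    ddm = c(ddm, list(cells_vz = ddm_cells_vz(ddm),
                      cells_at = ddm_cells_at(ddm))),
    latency = c(latency, list(cells = latency_cells(latency))),
    choice = c(choice, list(cells = choice_cells(choice))),
    subject_sd = subject_sd, lfp_burst = lfp_burst, sclera = sclera),
    class = "ground_truth")
  truth$contrasts <- true_contrasts(truth)
  truth
}

# Solve the symmetric link offset e such that g(l0 + e) - g(l0 - e) = target.
solve_offset <- function(target, l0, g) {
  if (target == 0) return(0)
  f <- function(e) g(l0 + e) - g(l0 - e) - target
  stats::uniroot(f, interval = c(-20, 20), tol = 1e-12)$root
}

ddm_cells_vz <- function(p) {
  cells <- cells_vz()
  lz <- rep(qlogis(p$z0), nrow(cells))
  # laterality contrast (Contra - Ipsi) on the native z scale, per instruction
  for (instr in c("Yield", "Oppose")) {
    target <- p$dz_lat_yield +
      if (instr == "Oppose") p$dz_instruction_x_lat else 0
    e <- solve_offset(target, qlogis(p$z0), plogis)
    sel_c <- cells$instruction == instr & cells$disruption == "Contra"
    sel_i <- cells$instruction == instr & cells$disruption == "Ipsi"
    lz[sel_c] <- qlogis(p$z0) + e
    lz[sel_i] <- qlogis(p$z0) - e
  }
  # drift per instruction: either given directly, or solved so the
  # absorption probability at the instruction's boundary separation and
  # central start point matches the stated fear-preference rate
  if (is.null(p$v0)) {
    solve_v <- function(target, a) {
      stats::uniroot(function(v) choice_prob_upper_cpp(v, a, p$z0) - target,
                     c(-10, 10), tol = 1e-12)$root
    }
    v_y <- solve_v(p$p_fear_yield, p$a0)
    v_o <- solve_v(p$p_fear_oppose, p$a0 + p$da_instruction)
    cells$v <- ifelse(cells$instruction == "Yield", v_y, v_o)
  } else {
    cells$v <- p$v0
  }
  cells$logit_z <- lz
  cells$z <- plogis(lz)
  cells
}

ddm_cells_at <- function(p) {
  cells <- cells_at()
  a <- ifelse(cells$instruction == "Oppose", p$a0 + p$da_instruction, p$a0)
  t0 <- ifelse(cells$presence == "Present", p$t00 + p$dt0_presence, p$t00)
  cells$log_a <- log(a); cells$a <- a
  cells$log_t0 <- log(t0); cells$t0 <- t0
  cells
}

latency_cells <- function(p) {
  cells <- cells_behaviour(c("fear", "neutral"), "emotion")
  mu0 <- log(p$median0)
  defs <- contrast_defs_behaviour(cells, "emotion", "fear")
  sgn <- function(lv, pos, neg) ifelse(lv == pos, 1, ifelse(lv == neg, -1, 0))
  # link-scale offset patterns, one per effect
  patterns <- list(
    disruption_presence = as.numeric(cells$disruption != "None"),
    f3_main = sgn(cells$emotion, "fear", "neutral"),
    laterality_yield = sgn(cells$disruption, "Contra", "Ipsi"),
    laterality_x_f3_yield = (cells$instruction == "Yield") *
      sgn(cells$disruption, "Contra", "Ipsi") *
      sgn(cells$emotion, "fear", "neutral"),
    instruction_x_laterality_x_f3 = (cells$instruction == "Oppose") *
      sgn(cells$disruption, "Contra", "Ipsi") *
      sgn(cells$emotion, "fear", "neutral"))
  targets <- c(disruption_presence = p$d_presence, f3_main = p$d_emotion,
               laterality_yield = p$d_lat_yield,
               laterality_x_f3_yield = p$d_lat_x_emotion_yield,
               instruction_x_laterality_x_f3 =
                 p$d_lat_x_emotion_yield + p$d_threeway)
  # the Oppose interaction pattern is checked against its own realized
  # value; the reported three-way contrast is (Oppose - Yield) pattern
  realize <- function(b) {
    mu <- mu0 + drop(do.call(cbind, patterns) %*% b)
    ems <- p$delta0 + exp(mu + p$sigma0^2 / 2)
    c(vapply(defs[names(targets)[1:4]], function(w) sum(w * ems), numeric(1)),
      instruction_x_laterality_x_f3 =
        sum((defs$instruction_x_laterality_x_f3 +
             defs$laterality_x_f3_yield) * ems))
  }
  # response-scale effects interact multiplicatively on the log link, so the
  # offsets are solved coordinate-wise against the realized contrasts
  b <- setNames(numeric(length(targets)), names(targets))
  for (round in 1:4) {
    for (j in seq_along(targets)) {
      f <- function(x) { bb <- b; bb[j] <- x; realize(bb)[j] - targets[j] }
      b[j] <- stats::uniroot(f, c(-2, 2), tol = 1e-12)$root
    }
  }
  cells$mu <- mu0 + drop(do.call(cbind, patterns) %*% b)
  cells$expected_ms <- p$delta0 + exp(cells$mu + p$sigma0^2 / 2)
  cells
}

choice_cells <- function(p) {
  cells <- cells_behaviour(c("Early", "Late"), "latbin")
  defs <- contrast_defs_behaviour(cells, "latbin", "Early")
  l0 <- ifelse(cells$instruction == "Yield", qlogis(p$theta_yield),
               qlogis(p$theta_oppose))
  sgn <- function(lv, pos, neg) ifelse(lv == pos, 1, ifelse(lv == neg, -1, 0))
  patterns <- list(
    f3_main = sgn(cells$latbin, "Early", "Late"),
    laterality_x_f3_yield = (cells$instruction == "Yield") *
      sgn(cells$disruption, "Contra", "Ipsi") * sgn(cells$latbin, "Early", "Late"),
    instruction_x_laterality_x_f3 = (cells$instruction == "Oppose") *
      sgn(cells$disruption, "Contra", "Ipsi") * sgn(cells$latbin, "Early", "Late"))
  targets <- c(f3_main = p$d_latbin,
               laterality_x_f3_yield = p$d_lat_x_bin_yield,
               instruction_x_laterality_x_f3 =
                 p$d_lat_x_bin_yield + p$d_threeway)
  realize <- function(b) {
    th <- plogis(l0 + drop(do.call(cbind, patterns) %*% b))
    c(f3_main = sum(defs$f3_main * th),
      laterality_x_f3_yield = sum(defs$laterality_x_f3_yield * th),
      instruction_x_laterality_x_f3 =
        sum((defs$instruction_x_laterality_x_f3 +
             defs$laterality_x_f3_yield) * th))
  }
  b <- setNames(numeric(length(targets)), names(targets))
  for (round in 1:4) {
    for (j in seq_along(targets)) {
      f <- function(x) { bb <- b; bb[j] <- x; realize(bb)[j] - targets[j] }
      b[j] <- stats::uniroot(f, c(-5, 5), tol = 1e-12)$root
    }
  }
  cells$logit_theta <- l0 + drop(do.call(cbind, patterns) %*% b)
  cells$theta <- plogis(cells$logit_theta)
  cells
}

# True values of every planned contrast, on the scale the analysis reports
# (latency in ms at the typical subject, choice as rates, z native, a native,
# t0 in ms), computed with the same weights the fitted models use.
true_contrasts <- function(truth) {
  lat <- truth$latency
  cl <- lat$cells
  defs <- contrast_defs_behaviour(cl, "emotion", "fear")
  latency <- vapply(defs, function(w) sum(w * cl$expected_ms), numeric(1))

  cc <- truth$choice$cells
  defs <- contrast_defs_behaviour(cc, "latbin", "Early")
  choice <- vapply(defs, function(w) sum(w * cc$theta), numeric(1))

  cvz <- truth$ddm$cells_vz
  dvz <- contrast_defs_vz(cvz)
  cat_ <- truth$ddm$cells_at
  dat <- contrast_defs_at(cat_)
  ddm <- c(
    setNames(vapply(dvz, function(w) sum(w * cvz$z), numeric(1)),
             paste0("z_", names(dvz))),
    setNames(vapply(dvz, function(w) sum(w * cvz$v), numeric(1)),
             paste0("v_", names(dvz))),
    setNames(vapply(dat, function(w) sum(w * cat_$a), numeric(1)),
             paste0("a_", names(dat))),
    setNames(vapply(dat, function(w) sum(w * cat_$t0 * 1000), numeric(1)),
             paste0("t0_", names(dat))))
  list(latency = latency, choice = choice, ddm = ddm)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic-experiment ground truth\n")
  cat(sprintf("  DDM base: v=%.3f a=%.3f z=%.3f t0=%.3f s; subject SD %.2f\n",
              x$ddm$v0, x$ddm$a0, x$ddm$z0, x$ddm$t00, x$subject_sd))
  cat(sprintf("  key effects: dz(lat,Yield)=%.3f, dt0(presence)=%.0f ms, ",
              x$contrasts$ddm["z_laterality_yield"],
              x$contrasts$ddm["t0_disruption_presence"]))
  cat(sprintf("dlatency(lat x emo,Yield)=%.1f ms\n",
              x$contrasts$latency["laterality_x_f3_yield"]))
  cat(sprintf("  LFP burst: %g Hz, %g +/- %g ms, +%g%%\n",
              x$lfp_burst$freq_hz, x$lfp_burst$center_ms, x$lfp_burst$sd_ms,
              x$lfp_burst$amplitude_pct))
  invisible(x)
}
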