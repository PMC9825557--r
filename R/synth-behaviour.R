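#' Simulate trial-level behaviour for a synthetic cohort
#'
#' Generates one choice and one latency per trial of `design` from the
#' generating model in `truth`, with zero-mean Normal subject intercept
#' deviations (SD `truth$subject_sd`) applied on each parameter's link scale.
#' Three generating modes are available, one per fitted model family:
#'
#' * `"ddm"` (default): the condition's Wiener parameters drive a diffusion
#'   race; the choice is the absorbed boundary (upper = fearful face) and the
#'   latency is `t0` plus the first-passage time, drawn by inverting the
#'   numerically integrated first-passage distribution.
#' * `"latency"`: the chosen emotion is a fair coin and the latency is drawn
#'   from the condition-by-emotion shifted-lognormal cells, the generating
#'   model of the latency analysis.
#' * `"choice"`: latencies come from an effect-free shifted lognormal, the
#'   within-cell median split labels trials Early/Late, and the choice is
#'   Bernoulli with the condition-by-latency-bin fear-preference rate.
#'
#' Every trial uses its own counter-based RNG substream, so generation is
#' reproducible and subsetting trials never shifts other trials' draws. Each
#' record carries a QC label derived from the generated latency by the
#' analysis rules (< 100 ms implausibly fast, > 1000 ms absent).
#'
#' @param design trial list from [make_design()].
#' @param truth a [ground_truth()] object.
#' @param seed integer seed for the behavioural draws.
#' @param generator generating model, see above.
#' @return A trial-record data.frame; the generating truth and the drawn
#'   subject deviations are attached as attributes.
#' @export
simulate_behaviour <- function(design, truth, seed = 1L,
                               generator = c("ddm", "latency", "choice")) {
  stopifnot(inherits(truth, "ground_truth"), is.data.frame(design))
  generator <- match.arg(generator)
  n <- nrow(design)
  design$trial_uid <- design$trial_uid %||% seq_len(n)
  subj <- sort(unique(design$participant))
  S <- length(subj)

  # subject deviations: one substream per participant, fixed slot order
  dev_names <- c("v", "z", "a", "t0", "mu", "lsigma", "ldelta", "ltheta")
  dev <- matrix(0, S, length(dev_names), dimnames = list(NULL, dev_names))
  dseed <- substream_seeds(seed, 2^20 + seq_len(S))
  for (s in seq_len(S))
    dev[s, ] <- with_seed(dseed[s], rnorm(length(dev_names), 0, truth$subject_sd))

  sidx <- match(design$participant, subj)
  tseed <- substream_seeds(seed, design$trial_uid)
  rec <- design
  rec$choice <- NA_character_
  rec$latency_ms <- NA_real_

  if (generator == "ddm") {
    cvz <- truth$ddm$cells_vz
    cat_ <- truth$ddm$cells_at
    ivz <- cell_index(design[c("instruction", "disruption", "hemifield_fear")],
                      cvz[c("instruction", "disruption", "hemifield")])
    iat <- cell_index(data.frame(instruction = design$instruction,
                                 presence = ifelse(design$disrupted, "Present", "None")),
                      cat_[c("instruction", "presence")])
    key <- paste(sidx, ivz, iat)
    for (k in unique(key)) {
      rows <- which(key == k)
      s <- sidx[rows[1]]; cv <- ivz[rows[1]]; ca <- iat[rows[1]]
      v <- cvz$v[cv] + dev[s, "v"]
      z <- plogis(cvz$logit_z[cv] + dev[s, "z"])
      a <- exp(log(cat_$a[ca]) + dev[s, "a"])
      t0 <- exp(log(cat_$t0[ca]) + dev[s, "t0"])
      g <- wfpt_cdf_grid_cpp(v, a, z, 2.5e-4)
      m <- length(g$t)
      for (i in rows) {
        u <- with_seed(tseed[i], runif(2))
        up <- u[1] < g$p_upper
        C <- if (up) g$cdf_upper else g$cdf_lower
        rt <- stats::approx(C, g$t, xout = u[2] * C[m], ties = "ordered")$y
        rec$choice[i] <- if (up) "fear" else "neutral"
        rec$latency_ms[i] <- (t0 + rt) * 1000
      }
    }
    rec$emotion <- rec$choice
  } else if (generator == "latency") {
    cl <- truth$latency$cells
    sig <- exp(log(truth$latency$sigma0) + dev[, "lsigma"])
    del <- exp(log(truth$latency$delta0) + dev[, "ldelta"])
    draw <- vapply(tseed, function(sd_) with_seed(sd_, c(runif(1), rnorm(1))),
                   numeric(2))
    emo <- ifelse(draw[1, ] < 0.5, "fear", "neutral")
    ci <- cell_index(data.frame(instruction = design$instruction,
                                disruption = design$disruption,
                                emotion = emo),
                     cl[c("instruction", "disruption", "emotion")])
    rec$emotion <- emo
    rec$choice <- emo
    rec$latency_ms <- del[sidx] +
      exp(cl$mu[ci] + dev[sidx, "mu"] + sig[sidx] * draw[2, ])
  } else { # choice
    sig <- truth$latency$sigma0
    mu0 <- log(truth$latency$median0)
    del <- exp(log(truth$latency$delta0) + dev[, "ldelta"])
    zdraw <- vapply(tseed, function(sd_) with_seed(sd_, c(rnorm(1), runif(1))),
                    numeric(2))
    rec$latency_ms <- del[sidx] + exp(mu0 + dev[sidx, "mu"] + sig * zdraw[1, ])
    rec$qc <- "valid"
    rec <- median_split(rec)
    cc <- truth$choice$cells
    ci <- cell_index(data.frame(instruction = rec$instruction,
                                disruption = rec$disruption,
                                latbin = rec$latbin),
                     cc[c("instruction", "disruption", "latbin")])
    theta <- plogis(cc$logit_theta[ci] + dev[sidx, "ltheta"])
    rec$choice <- ifelse(zdraw[2, ] < theta, "fear", "neutral")
    rec$emotion <- rec$choice
  }

  # QC labels from the analysis rules applied to the generated latency
  rec$qc <- ifelse(rec$latency_ms < 100, "too_fast",
                   ifelse(rec$latency_ms > 1000, "absent", "valid"))
  rec$choice[rec$qc == "absent"] <- "none"
  # direction of the executed saccade (positions are left/right on screen)
  rec$direction <- ifelse(rec$choice == "none", NA_character_,
                          ifelse((rec$choice == "fear") ==
                                   (rec$hemifield_fear == "R"), "R", "L"))
  attr(rec, "truth") <- truth
  attr(rec, "subject_dev") <- dev
  attr(rec, "generator") <- generator
  rec
}

#' Median split of latencies within factorial cells
#'
#' Adds a binarized-latency column (`latbin`, Early / Late) computed
#' independently within each Instruction x Disruption x Hemifield cell over
#' valid trials, so the label is orthogonal to the design factors. Trials
#' strictly below the cell median are Early; values at or above the median
#' (including the median itself, the deterministic tie rule) are Late.
#'
#' @param table a trial-record data.frame with `latency_ms` and `qc` columns
#'   (rows with `qc != "valid"` keep `latbin = NA`).
#' @return The table with a `latbin` column added.
#' @export
median_split <- function(table) {
  stopifnot(is.data.frame(table), all(c("latency_ms", "qc") %in% names(table)))
  cellkey <- paste(table$instruction, table$disruption, table$hemifield_fear)
  table$latbin <- NA_character_
  for (k in unique(cellkey)) {
    rows <- which(cellkey == k & table$qc == "valid" & !is.na(table$latency_ms))
    if (!length(rows)) stop("factorial cell without valid latencies: ", k)
    med <- stats::median(table$latency_ms[rows])
    table$latbin[rows] <- ifelse(table$latency_ms[rows] < med, "Early", "Late")
  }
  table
}
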