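# Induced time-frequency analysis of the bipolar amygdala channel.

#' Preprocess raw channels into fixed-window epochs
#'
#' Re-references to a bipolar montage of the two most distal contacts (the
#' first two rows), applies a 0.1 Hz two-pass fifth-order Butterworth
#' high-pass (zero-phase), and epochs -2 to +4 s around each event.
#'
#' @param raw matrix (contacts x samples) or numeric vector (already
#'   bipolar).
#' @param events event sample indices (triggers).
#' @param fs sampling rate (default 1024).
#' @param labels optional data.frame of per-event condition labels, carried
#'   onto the epochs.
#' @param trigger `"stimulus"` or `"saccade"`, a tag only.
#' @return list of `lfp_epoch` objects (6 x fs samples each).
#' @export
lfp_preprocess <- function(raw, events, fs = 1024, labels = NULL,
                           trigger = c("stimulus", "saccade")) {
  trigger <- match.arg(trigger)
  x <- if (is.matrix(raw)) {
    if (nrow(raw) < 2) stop("need >= 2 contacts or an already-bipolar vector")
    raw[1, ] - raw[2, ]
  } else as.numeric(raw)
  # zero-phase (two-pass) fifth-order Butterworth high-pass, applied as a
  # cascade of second-order sections: at 0.1 Hz / 1024 Hz the single
  # transfer-function form is numerically unstable
  for (sec in butter_hp_sections(5, 0.1, fs)) {
    x <- signal::filtfilt(sec$b, sec$a, x)
  }
  n <- length(x)
  pre <- 2 * fs; post <- 4 * fs
  out <- vector("list", length(events))
  for (i in seq_along(events)) {
    ev <- events[i]
    if (ev - pre < 1 || ev + post - 1 > n)
      stop("event ", i, " too close to the recording edge")
    ep <- structure(list(x = x[(ev - pre):(ev + post - 1)], fs = fs, t0 = -2,
                         trigger = trigger), class = "lfp_epoch")
    if (!is.null(labels)) ep[names(labels)] <- as.list(labels[i, ])
    out[[i]] <- ep
  }
  out
}

# Butterworth high-pass as biquad sections (analog prototype, high-pass
# transform, bilinear), numerically robust for very low cutoffs.
butter_hp_sections <- function(order, fc, fs) {
  wc <- 2 * fs * tan(pi * fc / fs) # prewarped analog cutoff (rad/s)
  K <- 2 * fs
  sections <- list()
  for (k in seq_len(order %/% 2)) {
    th <- pi * (2 * k + order - 1) / (2 * order)
    a1 <- -2 * cos(th) * wc        # > 0 for a stable pole pair
    a0 <- wc^2
    a0d <- K^2 + a1 * K + a0
    sections[[k]] <- list(
      b = c(K^2, -2 * K^2, K^2) / a0d,
      a = c(1, (-2 * K^2 + 2 * a0) / a0d, (K^2 - a1 * K + a0) / a0d))
  }
  if (order %% 2 == 1) {
    a0d <- K + wc
    sections[[length(sections) + 1]] <-
      list(b = c(K, -K) / a0d, a = c(1, (wc - K) / a0d))
  }
  sections
}

# Discrete prolate spheroidal sequences via the symmetric tridiagonal form;
# returns n x k matrix of unit-energy tapers.
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  i <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- (i[-1] * (n - i[-1]))[] / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_v
  A[cbind(seq_len(n - 1), 2:n)] <- off_v
  A[cbind(2:n, seq_len(n - 1))] <- off_v
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  tap
}

.tfr_cache <- new.env(parent = emptyenv())

band_config <- function(band, fs) {
  key <- paste(band, fs)
  if (!is.null(.tfr_cache[[key]])) return(.tfr_cache[[key]])
  cfg <- if (band == "high") {
    wlen <- round(0.2 * fs)          # 200 ms window
    list(wlen = wlen, tapers = dpss_tapers(wlen, 2, 3), # +/-10 Hz smoothing
         freq = seq(52, 148, by = 4), fres = 4)
  } else {
    wlen <- round(0.4 * fs)          # 400 ms window, ~5 Hz resolution
    h <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
    list(wlen = wlen, tapers = matrix(h / sqrt(sum(h^2)), ncol = 1),
         freq = seq(2, 48, by = 2), fres = 2)
  }
  # complex exponential basis evaluating the DFT only at the band's
  # frequency bins (cheaper than padded full FFTs)
  tt <- (seq_len(cfg$wlen) - 1) / fs
  cfg$basis <- exp(-2i * pi * outer(cfg$freq, tt))   # F x wlen
  .tfr_cache[[key]] <- cfg
  cfg
}

#' Single-trial spectrogram (Hanning low band / DPSS multitaper high band)
#'
#' Low band (1-48 Hz): single Hanning taper, 400 ms sliding window. High
#' band (52-148 Hz): discrete prolate spheroidal sequence multitapers
#' (time-bandwidth 2, 3 tapers, i.e. +/-10 Hz smoothing), 200 ms window.
#' Both bands step in 25 ms; window centres snap to the nearest sample.
#'
#' @param epoch an `lfp_epoch`, or a numeric vector with `fs`/`t0` given.
#' @param band `"high"` or `"low"`.
#' @param toi time axis (s relative to trigger), 25 ms steps by default.
#' @param fs,t0 sampling rate and epoch start, read from `epoch` if absent.
#' @return list of class `tfr_image`: `power` (freq x time), `freq`, `time`,
#'   `band`.
#' @export
tfr_spectrogram <- function(epoch, band = c("high", "low"),
                            toi = seq(-1, 1, by = 0.025),
                            fs = NULL, t0 = NULL) {
  band <- match.arg(band)
  if (inherits(epoch, "lfp_epoch")) {
    x <- epoch$x; fs <- epoch$fs; t0 <- epoch$t0
  } else {
    x <- as.numeric(epoch)
    if (is.null(fs)) stop("fs required for a bare vector")
    if (is.null(t0)) t0 <- 0
  }
  cfg <- band_config(band, fs)
  half <- cfg$wlen %/% 2
  centre <- round((toi - t0) * fs) + 1L
  if (any(centre - half < 1) || any(centre + half > length(x)))
    stop("epoch too short for the requested time axis")
  off <- seq_len(cfg$wlen) - 1L - half
  seg <- matrix(x[outer(off, centre, "+")], cfg$wlen, length(centre))
  pow <- 0
  for (k in seq_len(ncol(cfg$tapers))) {
    sp <- cfg$basis %*% (seg * cfg$tapers[, k])
    pow <- pow + Mod(sp)^2
  }
  structure(list(power = pow / ncol(cfg$tapers), freq = cfg$freq, time = toi,
                 band = band), class = "tfr_image")
}

#' Robust (bisquare-weighted) average of trial spectrograms
#'
#' Iteratively reweighted mean across trials, pixelwise: residuals are
#' standardized by the pixel's median absolute deviation and downweighted by
#' Tukey's bisquare (tuning constant 4.685, at most 20 iterations). Weights
#' lie in `[0, 1]`; with identical trials (or no outliers beyond the tuning
#' constant) the result equals the arithmetic mean.
#'
#' @param tfs list of `tfr_image`s (same grid), or a trials x pixels matrix.
#' @param c_tuning bisquare tuning constant.
#' @param max_iter maximum reweighting iterations.
#' @return A `tfr_image` with the robust mean (`power`) and the final
#'   `weights` (trials x pixels), or a list(`mean`, `weights`) for matrix
#'   input.
#' @export
robust_average <- function(tfs, c_tuning = 4.685, max_iter = 20) {
  as_img <- is.list(tfs) && inherits(tfs[[1]], "tfr_image")
  if (as_img) {
    proto <- tfs[[1]]
    X <- t(vapply(tfs, function(tf) as.vector(tf$power),
                  numeric(length(proto$power))))
  } else X <- as.matrix(tfs)
  if (nrow(X) < 3) stop("robust averaging needs at least 3 trials")
  W <- matrix(1, nrow(X), ncol(X))
  m <- colMeans(X)
  for (it in seq_len(max_iter)) {
    R <- sweep(X, 2, m)
    s <- apply(abs(R), 2, stats::median) / 0.6745
    s[s <= 0] <- Inf              # identical trials: all weights stay 1
    U <- abs(sweep(R, 2, s, "/")) / c_tuning
    W <- ifelse(U < 1, (1 - U^2)^2, 0)
    m_new <- colSums(W * X) / pmax(colSums(W), .Machine$double.eps)
    if (max(abs(m_new - m), na.rm = TRUE) < 1e-10 * max(abs(m), 1)) {
      m <- m_new; break
    }
    m <- m_new
  }
  if (as_img) {
    out <- proto
    out$power <- matrix(m, nrow(proto$power), ncol(proto$power))
    out$weights <- W
    out
  } else list(mean = m, weights = W)
}

#' Rescale a time-frequency image to percent change over baseline
#'
#' Per frequency row, `100 * (power - baseline mean) / baseline mean`, with
#' the baseline mean taken over the given pre-stimulus window.
#'
#' @param tf a `tfr_image`.
#' @param baseline_window two times (s), default -0.6 to -0.2.
#' @return The rescaled `tfr_image` (values in percent).
#' @export
baseline_rescale <- function(tf, baseline_window = c(-0.6, -0.2)) {
  sel <- tf$time >= baseline_window[1] & tf$time <= baseline_window[2]
  if (!any(sel)) stop("baseline window outside the image time axis")
  b <- rowMeans(tf$power[, sel, drop = FALSE])
  if (any(b <= 0)) stop("zero baseline power")
  tf$power <- 100 * sweep(sweep(tf$power, 1, b), 1, b, "/")
  tf$baselined <- TRUE
  tf
}

#' Condition-average percent-change image for one participant
#'
#' The per-condition pipeline: single-trial spectrograms, robust averaging,
#' percent-change baseline rescaling, and Gaussian smoothing (FWHM 4 x 2
#' frequency x time pixels in the high band, 3 x 2 in the low band).
#'
#' @param epochs list of `lfp_epoch`s belonging to one participant x
#'   condition cell.
#' @param band `"high"` or `"low"`.
#' @param toi time axis (s).
#' @param smooth_fwhm FWHM in (frequency, time) pixels; `NULL` for the
#'   band default.
#' @return A smoothed percent-change `tfr_image`.
#' @export
tfr_condition_image <- function(epochs, band = c("high", "low"),
                                toi = seq(-1, 1, by = 0.025),
                                smooth_fwhm = NULL) {
  band <- match.arg(band)
  if (is.null(smooth_fwhm)) smooth_fwhm <- if (band == "high") c(4, 2) else c(3, 2)
  tfs <- lapply(epochs, tfr_spectrogram, band = band, toi = toi)
  avg <- robust_average(tfs)
  img <- baseline_rescale(avg)
  img$power <- smooth2d(img$power, smooth_fwhm)
  img
}

#' Per-participant condition images for a cohort of epochs
#'
#' Groups epochs by participant and Recording side x Emotion cell and runs
#' [tfr_condition_image()] on each, producing the nested list that
#' [tfr_anova()] consumes.
#'
#' @param epochs list of `lfp_epoch`s carrying `participant`,
#'   `recording_side` and `emotion` labels.
#' @param band,toi passed to [tfr_condition_image()].
#' @return nested list `images[[participant]][[side.emotion]]`.
#' @export
tfr_cohort_images <- function(epochs, band = "high",
                              toi = seq(-1, 1, by = 0.025)) {
  parts <- sort(unique(vapply(epochs, `[[`, numeric(1), "participant")))
  lab <- paste(vapply(epochs, `[[`, character(1), "recording_side"),
               vapply(epochs, `[[`, character(1), "emotion"), sep = ".")
  pid <- vapply(epochs, `[[`, numeric(1), "participant")
  cells <- c("Contra.fear", "Contra.neutral", "Ipsi.fear", "Ipsi.neutral")
  out <- lapply(parts, function(p) {
    im <- lapply(cells, function(cl) {
      sel <- which(pid == p & lab == cl)
      if (length(sel) < 3)
        stop("participant ", p, " has fewer than 3 trials in cell ", cl)
      tfr_condition_image(epochs[sel], band = band, toi = toi)
    })
    names(im) <- cells
    im
  })
  names(out) <- paste0("P", parts)
  out
}

#' Within-subject 2 x 2 factorial inference on time-frequency images
#'
#' Tests the Recording side (ipsi/contralateral to the fearful face) by
#' Emotion (of the oriented target) interaction pixelwise within the 0-400 ms
#' post-stimulus mask. Per participant the interaction contrast
#' `(Contra,fear) - (Contra,neutral) - (Ipsi,fear) + (Ipsi,neutral)` is
#' formed; the group statistic is the one-sample F (squared t) across
#' participants. Family-wise error is controlled by a max-statistic
#' permutation null over within-participant condition exchanges (sign flips
#' of the interaction contrast).
#'
#' @param images nested list: `images[[participant]][[cell]]` with cells
#'   named `Contra.fear`, `Contra.neutral`, `Ipsi.fear`, `Ipsi.neutral`,
#'   each a `tfr_image` on a common grid.
#' @param mask_window time window (s) for inference, default 0 to 0.4.
#' @param n_perm number of sign-flip permutations (>= 1000 recommended).
#' @param alpha family-wise error level.
#' @param seed permutation seed.
#' @return list of class `tfr_anova`: `F` map, `df`, `mask`, `threshold`
#'   (FWE), `sig` map, `peak` (freq, time, F, p_fwe), and `marginals`
#'   (per-cell mean and SE traces at the peak frequency).
#' @export
tfr_anova <- function(images, mask_window = c(0, 0.4), n_perm = 1000,
                      alpha = 0.05, seed = 1L) {
  cells <- c("Contra.fear", "Contra.neutral", "Ipsi.fear", "Ipsi.neutral")
  S <- length(images)
  proto <- images[[1]][[cells[1]]]
  if (any(!vapply(images, function(im) all(cells %in% names(im)), logical(1))))
    stop("missing condition cell for at least one participant")
  P <- length(proto$power)
  con <- matrix(NA_real_, S, P)
  for (s in seq_len(S)) {
    im <- images[[s]]
    con[s, ] <- as.vector(im$Contra.fear$power) -
      as.vector(im$Contra.neutral$power) -
      as.vector(im$Ipsi.fear$power) + as.vector(im$Ipsi.neutral$power)
  }
  tmap <- colMeans(con) / (apply(con, 2, sd) / sqrt(S))
  Fmap <- matrix(tmap^2, nrow(proto$power), ncol(proto$power))
  mask <- matrix(rep(proto$time >= mask_window[1] & proto$time <= mask_window[2],
                     each = nrow(proto$power)),
                 nrow(proto$power), ncol(proto$power))

  # max-F null over within-participant exchanges of the side labels
  # (sign flips of the interaction contrast); vectorized: under a flip the
  # per-pixel mean square is invariant, so every permutation's t map comes
  # from one matrix product
  set.seed(seed)
  idx <- which(as.vector(mask))
  conm <- con[, idx, drop = FALSE]
  Fl <- matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S)
  M <- (Fl %*% conm) / S                       # permuted means
  msq <- colMeans(conm^2)                      # invariant mean square
  Vp <- sweep(-M^2, 2, msq, "+") * S / (S - 1) # permuted variances
  Tp2 <- S * M^2 / Vp
  maxF <- apply(Tp2, 1, max)
  thr <- unname(quantile(maxF, 1 - alpha, type = 7))
  sig <- Fmap >= thr & mask
  Fm <- ifelse(mask, Fmap, NA_real_)
  pk <- which(Fm == max(Fm, na.rm = TRUE), arr.ind = TRUE)[1, ]
  p_fwe <- (1 + sum(maxF >= Fmap[pk[1], pk[2]])) / (n_perm + 1)
  peak <- data.frame(freq = proto$freq[pk[1]], time = proto$time[pk[2]],
                     F = Fmap[pk[1], pk[2]], p_fwe = p_fwe)

  marg <- lapply(cells, function(cl) {
    tr <- t(vapply(images, function(im) im[[cl]]$power[pk[1], ],
                   numeric(ncol(proto$power))))
    data.frame(time = proto$time, mean = colMeans(tr),
               se = apply(tr, 2, sd) / sqrt(S))
  })
  names(marg) <- cells

  structure(list(F = Fmap, t = matrix(tmap, nrow(proto$power)),
                 df = c(1, S - 1), mask = mask, threshold = thr, sig = sig,
                 peak = peak, marginals = marg, freq = proto$freq,
                 time = proto$time, n_perm = n_perm, alpha = alpha),
            class = "tfr_anova")
}

#' @export
print.tfr_anova <- function(x, ...) {
  cat(sprintf("2x2 within-subject TF interaction: F(%d,%d), %d permutations\n",
              x$df[1], x$df[2], x$n_perm))
  cat(sprintf("  peak: %g Hz at %g ms, F = %.2f, p(FWE) = %.3f%s\n",
              x$peak$freq, x$peak$time * 1000, x$peak$F, x$peak$p_fwe,
              if (x$peak$p_fwe <= x$alpha) " *" else ""))
  cat(sprintf("  %d suprathreshold pixels (threshold %.2f)\n",
              sum(x$sig), x$threshold))
  invisible(x)
}
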