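# Pixelwise fixed-effects inference on face difference images.

facepix_design <- function(labels) {
  disruption <- factor(labels$disruption, levels = f_lvl$disruption)
  latbin <- factor(labels$latbin, levels = f_lvl$latbin)
  if (anyNA(disruption) || anyNA(latbin)) stop("missing design labels")
  cellf <- interaction(disruption, latbin, sep = ".")
  X <- stats::model.matrix(~ 0 + cellf)
  colnames(X) <- levels(cellf)
  side <- ifelse(labels$side == "R", 0.5, -0.5) # orientation-side confound
  X <- cbind(X, side = side)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  X
}

facepix_stats <- function(Y, X, cellnames) {
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  B <- XtXi %*% crossprod(X, Y)            # coefficients x pixels
  resid <- Y - X %*% B
  df2 <- nrow(X) - ncol(X)
  s2 <- colSums(resid^2) / df2
  # per-disruption Early - Late contrasts
  lv <- f_lvl$disruption
  Cmat <- t(vapply(lv, function(dlev) {
    w <- setNames(numeric(ncol(X)), colnames(X))
    w[paste0(dlev, ".Early")] <- 1
    w[paste0(dlev, ".Late")] <- -1
    w
  }, numeric(ncol(X))))
  est <- Cmat %*% B                         # 3 x pixels
  tden <- sqrt(diag(Cmat %*% XtXi %*% t(Cmat)))
  tmaps <- est / (tden %o% sqrt(s2))
  # omnibus: the three Early-Late effects jointly
  M <- solve(Cmat %*% XtXi %*% t(Cmat))
  Fmap <- colSums((M %*% est) * est) / (nrow(Cmat) * s2)
  list(tmaps = tmaps, Fmap = Fmap, df = c(nrow(Cmat), df2), B = B)
}

#' Pixelwise linear fixed-effects model on face difference images
#'
#' Fits, at every pixel, an ordinary least-squares model of the
#' attended-minus-neglected intensity with Disruption (None / Ipsilateral /
#' Contralateral to the fearful face) by binarized Latency (Early / Late)
#' cells and the orientation side as a confound. Emits the three
#' per-disruption Early-minus-Late t maps and their joint (omnibus) F map.
#'
#' @param images list of `diff_image`s sharing one frame (>= 2 per cell).
#' @return list of class `facepix_glm`: `tmaps` (named list of matrices),
#'   `Fmap`, `df`, the design and data (for permutation), `dims`.
#' @export
fit_pixelwise_glm <- function(images) {
  labels <- do.call(rbind, lapply(images, `[[`, "labels"))
  dims <- dim(images[[1]]$pixels)
  Y <- t(vapply(images, function(im) as.vector(im$pixels),
                numeric(prod(dims))))
  counts <- table(labels$disruption, labels$latbin)
  if (any(counts < 2)) stop("need >= 2 images per design cell")
  X <- facepix_design(labels)
  st <- facepix_stats(Y, X, colnames(X))
  tmaps <- lapply(seq_len(3), function(i) matrix(st$tmaps[i, ], dims[1], dims[2]))
  names(tmaps) <- paste0("EarlyVsLate_", f_lvl$disruption)
  structure(list(tmaps = tmaps, Fmap = matrix(st$Fmap, dims[1], dims[2]),
                 df = st$df, Y = Y, labels = labels, dims = dims),
            class = "facepix_glm")
}

#' @export
print.facepix_glm <- function(x, ...) {
  cat(sprintf("pixelwise GLM: %d images, %d x %d pixels, omnibus F(%d,%d) max %.2f\n",
              nrow(x$Y), x$dims[1], x$dims[2], x$df[1], x$df[2], max(x$Fmap)))
  invisible(x)
}

#' Permutation family-wise-error threshold for a pixelwise stat map
#'
#' Max-statistic permutation inference: the Early/Late labels are permuted
#' within Disruption x orientation-side blocks (the exchangeable units are
#' trials within a condition), the statistic map is recomputed, and its
#' maximum over the mask forms the null. Pixels outside the mask are never
#' suprathreshold; the observed peak gets a corrected p value.
#'
#' @param fit a `facepix_glm`.
#' @param statistic `"omnibus"` (F) or one of the disruption levels (the
#'   corresponding Early-Late t map, two-sided).
#' @param mask logical matrix (e.g. [upper_face_mask()]); inference is
#'   restricted to it.
#' @param n_perm number of permutations (>= 1000 for reporting).
#' @param alpha family-wise error level.
#' @param seed permutation seed.
#' @return list of class `facepix_fwe`: `stat` (masked map), `threshold`,
#'   `sig`, `peak` (row, col, stat, p_fwe), `null_max`.
#' @export
fwe_threshold <- function(fit, statistic = "omnibus", mask, n_perm = 1000,
                          alpha = 0.05, seed = 1L) {
  stopifnot(inherits(fit, "facepix_glm"))
  if (!any(mask)) stop("empty mask")
  midx <- which(as.vector(mask))
  obs <- if (statistic == "omnibus") as.vector(fit$Fmap) else {
    if (!statistic %in% f_lvl$disruption) stop("unknown statistic")
    abs(as.vector(fit$tmaps[[paste0("EarlyVsLate_", statistic)]]))
  }
  labels <- fit$labels
  blocks <- interaction(labels$disruption, labels$side)
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    lab_p <- labels
    lab_p$latbin <- ave(labels$latbin, blocks,
                        FUN = function(v) v[sample.int(length(v))])
    Xp <- facepix_design(lab_p)
    st <- facepix_stats(fit$Y[, midx, drop = FALSE], Xp, colnames(Xp))
    null_max[p] <- if (statistic == "omnibus") max(st$Fmap) else {
      i <- match(statistic, f_lvl$disruption)
      max(abs(st$tmaps[i, ]))
    }
  }
  thr <- unname(quantile(null_max, 1 - alpha, type = 7))
  stat_m <- matrix(NA_real_, fit$dims[1], fit$dims[2])
  stat_m[midx] <- obs[midx]
  sig <- !is.na(stat_m) & stat_m >= thr
  pk <- which(stat_m == max(stat_m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  p_fwe <- (1 + sum(null_max >= stat_m[pk[1], pk[2]])) / (n_perm + 1)
  structure(list(stat = stat_m, threshold = thr, sig = sig,
                 peak = data.frame(row = pk[1], col = pk[2],
                                   stat = stat_m[pk[1], pk[2]], p_fwe = p_fwe),
                 null_max = null_max, statistic = statistic, alpha = alpha,
                 n_perm = n_perm),
            class = "facepix_fwe")
}

#' @export
print.facepix_fwe <- function(x, ...) {
  cat(sprintf("max-statistic permutation FWE (%s, %d permutations)\n",
              x$statistic, x$n_perm))
  cat(sprintf("  peak %.2f at (%d, %d), p(FWE) = %.3f%s; threshold %.2f\n",
              x$peak$stat, x$peak$row, x$peak$col, x$peak$p_fwe,
              if (x$peak$p_fwe <= x$alpha) " *" else "", x$threshold))
  invisible(x)
}
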