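# Internal utilities: RNG substreams, windowed helpers, 2-D smoothing.

# Derive independent per-unit RNG seeds from a master seed and unit counters.
# Counter-based hashing means a unit's stream depends only on (master, counter),
# so subsetting or reordering units never shifts any other unit's draws.
substream_seeds <- function(master, counters) {
  stopifnot(is.numeric(master), length(master) == 1)
  substream_seed_cpp(as.integer(master), as.integer(counters))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# 1-D Gaussian kernel with given FWHM (in sample units), truncated at 4 SD.
gauss_kernel <- function(fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable 2-D Gaussian smoothing with border renormalization (the kernel is
# re-scaled over the in-image support so flat fields stay flat at the edges).
smooth2d <- function(img, fwhm = c(3, 2)) {
  sm1 <- function(m, k) {
    if (length(k) == 1) return(m)
    r <- (length(k) - 1) / 2
    n <- nrow(m)
    pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    ones <- rbind(matrix(0, r, ncol(m)), matrix(1, n, ncol(m)), matrix(0, r, ncol(m)))
    num <- apply(pad, 2, function(col) stats::filter(col, k, sides = 2))
    den <- apply(ones, 2, function(col) stats::filter(col, k, sides = 2))
    (num / den)[(r + 1):(r + n), , drop = FALSE]
  }
  out <- sm1(img, gauss_kernel(fwhm[1]))
  t(sm1(t(out), gauss_kernel(fwhm[2])))
}

# Runs of TRUE in a logical vector -> data.frame(start, end) of indices.
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
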