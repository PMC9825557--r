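test_that("preprocessing re-references, filters and epochs correctly", {
  fs <- 1024
  n <- 10 * fs
  set.seed(1)
  ch <- rnorm(n)
  raw <- rbind(ch, ch)                   # identical contacts
  ep <- lfp_preprocess(raw, events = 3 * fs, fs = fs)
  expect_equal(length(ep), 1)
  expect_equal(length(ep[[1]]$x), 6 * fs) # -2..+4 s at 1024 Hz
  expect_true(all(abs(ep[[1]]$x) < 1e-8)) # bipolar of identical channels
  # a constant offset is removed by the high-pass; the record must exceed
  # the 0.1 Hz settling time for the interior to reach steady state
  ep2 <- lfp_preprocess(rnorm(40 * fs) + 50, events = 20 * fs, fs = fs)
  mid <- ep2[[1]]$x[1000:5000]
  expect_lt(abs(mean(mid)), 0.5)
  expect_error(lfp_preprocess(raw, events = fs, fs = fs), "edge")
  expect_error(lfp_preprocess(raw[1, , drop = FALSE], events = 3 * fs, fs = fs),
               "contacts")
})

test_that("spectrograms concentrate energy at the driving frequency", {
  fs <- 1024
  t <- seq(0, 6 - 1 / fs, by = 1 / fs) - 2
  x20 <- sin(2 * pi * 20 * t)
  tf <- tfr_spectrogram(x20, band = "low", fs = fs, t0 = -2)
  expect_equal(tf$freq[which.max(rowMeans(tf$power))], 20)
  zero <- tfr_spectrogram(numeric(6 * fs), band = "high", fs = fs, t0 = -2)
  expect_true(all(zero$power == 0))
  x99 <- sin(2 * pi * 99 * t)
  tfh <- tfr_spectrogram(x99, band = "high", fs = fs, t0 = -2)
  pk <- tfh$freq[which.max(rowMeans(tfh$power))]
  expect_gte(pk, 95); expect_lte(pk, 105)
  # time axes are identical across calls (pixelwise algebra contract)
  expect_identical(tf$time, tfr_spectrogram(x20, "low", fs = fs, t0 = -2)$time)
})

test_that("white-noise average spectrogram is flat across frequency", {
  fs <- 1024
  set.seed(4)
  pows <- 0
  for (i in 1:200) {
    tf <- tfr_spectrogram(rnorm(3 * fs), band = "high", fs = fs, t0 = -1,
                          toi = seq(-0.4, 0.4, 0.025))
    pows <- pows + rowMeans(tf$power)
  }
  pows <- pows / 200
  expect_lt(max(abs(pows - mean(pows)) / mean(pows)), 0.1)
})

test_that("robust averaging downweights artefactual trials", {
  set.seed(5)
  clean <- matrix(rnorm(20 * 50, mean = 10), 20, 50)
  ra <- robust_average(clean)
  # clean data: close to the arithmetic mean, nothing fully rejected
  expect_equal(ra$mean, colMeans(clean), tolerance = 0.05)
  expect_true(all(ra$weights > 0))
  ident <- matrix(rep(1:50, each = 5), 5, 50)
  ri <- robust_average(ident)
  expect_identical(ri$mean, colMeans(ident))
  expect_true(all(ri$weights == 1))
  dirty <- rbind(clean, clean[1, ] * 100)
  rd <- robust_average(dirty)
  err_rob <- abs(rd$mean - colMeans(clean))
  err_ari <- abs(colMeans(dirty) - colMeans(clean))
  expect_gt(mean(err_rob < err_ari), 0.5)
  expect_true(all(rd$weights >= 0 & rd$weights <= 1))
  expect_error(robust_average(clean[1:2, ]), "3 trials")
})

test_that("baseline rescaling yields percent change per frequency", {
  tf <- structure(list(power = matrix(2, 4, 9), freq = 1:4,
                       time = seq(-0.8, 0.8, 0.2), band = "low"),
                  class = "tfr_image")
  r <- baseline_rescale(tf)
  expect_true(all(r$power == 0))
  tf$power[, tf$time > 0] <- 4      # doubled power post-stimulus
  r2 <- baseline_rescale(tf)
  expect_true(all(r2$power[, tf$time > 0] == 100))
  tf$power[1, ] <- 0
  expect_error(baseline_rescale(tf), "baseline")
})

test_that("percent-change images are invariant to signal gain", {
  fs <- 1024
  set.seed(6)
  x <- amygaze:::pink_noise(6 * fs, fs)
  toi <- seq(-0.8, 0.8, 0.025)
  p1 <- tfr_spectrogram(x, "high", fs = fs, t0 = -2, toi = toi)
  p2 <- tfr_spectrogram(3 * x, "high", fs = fs, t0 = -2, toi = toi)
  expect_equal(p2$power, 9 * p1$power, tolerance = 1e-10)
  expect_equal(baseline_rescale(p2)$power, baseline_rescale(p1)$power,
               tolerance = 1e-8)
})

test_that("the factorial interaction map is valid and guarded", {
  set.seed(7)
  cells <- c("Contra.fear", "Contra.neutral", "Ipsi.fear", "Ipsi.neutral")
  mk <- function() {
    structure(list(power = matrix(rnorm(20 * 33), 20, 33), freq = seq(52, 128, 4),
                   time = seq(-0.2, 0.6, 0.025), band = "high"),
              class = "tfr_image")
  }
  imgs <- lapply(1:8, function(s) setNames(lapply(cells, function(c) mk()), cells))
  an <- tfr_anova(imgs, n_perm = 200, seed = 2)
  expect_true(all(an$F >= 0))
  expect_equal(an$df, c(1, 7))
  expect_true(all(!an$sig[!an$mask]))
  bad <- imgs
  bad[[1]] <- bad[[1]][1:3]
  expect_error(tfr_anova(bad, n_perm = 50), "missing condition cell")
})
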