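# small image geometry keeps the pixelwise tests quick
fp_params <- face_image_params(height = 24, width = 20)

fp_cohort <- function(truth, n_per_cell = 6, seed = 1) {
  grid <- expand.grid(disruption = c("None", "Ipsi", "Contra"),
                      latbin = c("Early", "Late"),
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  grid$direction <- ifelse(grid$rep %% 2 == 0, "L", "R")
  lapply(seq_len(nrow(grid)), function(i)
    synth_face_pair(grid[i, ], truth, fp_params, seed = seed * 1000 + i))
}

test_that("difference images are reproducible and null without an effect", {
  tr0 <- ground_truth(sclera = list(amplitude = 0))
  rec <- data.frame(disruption = "Ipsi", latbin = "Early", direction = "R")
  i1 <- synth_face_pair(rec, tr0, fp_params, seed = 3)
  i2 <- synth_face_pair(rec, tr0, fp_params, seed = 3)
  expect_identical(i1$pixels, i2$pixels)
  imgs <- fp_cohort(tr0, n_per_cell = 10, seed = 5)
  grand <- mean(vapply(imgs, function(im) mean(im$pixels), numeric(1)))
  expect_lt(abs(grand), 0.1)
})

test_that("a null cohort's omnibus F map has its expected mean", {
  tr0 <- ground_truth(sclera = list(amplitude = 0))
  fit <- fit_pixelwise_glm(fp_cohort(tr0, n_per_cell = 8, seed = 7))
  df2 <- fit$df[2]
  expect_equal(mean(fit$Fmap), df2 / (df2 - 2), tolerance = 0.25)
  expect_true(all(fit$Fmap >= 0))
})

test_that("statistics are invariant to a constant intensity offset", {
  tr <- fx_truth()
  imgs <- fp_cohort(tr, seed = 9)
  fit1 <- fit_pixelwise_glm(imgs)
  shifted <- lapply(imgs, function(im) { im$pixels <- im$pixels + 5; im })
  fit2 <- fit_pixelwise_glm(shifted)
  expect_equal(fit1$Fmap, fit2$Fmap, tolerance = 1e-8)
})

test_that("an injected scleral effect is localized inside the mask", {
  tr <- ground_truth(sclera = list(amplitude = 2))
  fit <- fit_pixelwise_glm(fp_cohort(tr, n_per_cell = 8, seed = 11))
  tmap <- fit$tmaps$EarlyVsLate_Ipsi
  mask <- sclera_mask(fp_params)
  pk <- which(tmap == max(tmap), arr.ind = TRUE)
  expect_true(mask[pk[1], pk[2]])
  fwe <- fwe_threshold(fit, "Ipsi", upper_face_mask(fp_params),
                       n_perm = 300, seed = 1)
  expect_lte(fwe$peak$p_fwe, 0.05)
  # a mask that excludes the effect detects nothing
  lower <- !upper_face_mask(fp_params)
  fwe2 <- fwe_threshold(fit, "Ipsi", lower, n_perm = 300, seed = 1)
  expect_gt(fwe2$peak$p_fwe, 0.05)
  expect_true(all(is.na(fwe2$stat[upper_face_mask(fp_params)])))
})

test_that("permutation inference is reproducible under a fixed seed", {
  tr <- fx_truth()
  fit <- fit_pixelwise_glm(fp_cohort(tr, seed = 13))
  f1 <- fwe_threshold(fit, "omnibus", upper_face_mask(fp_params),
                      n_perm = 200, seed = 4)
  f2 <- fwe_threshold(fit, "omnibus", upper_face_mask(fp_params),
                      n_perm = 200, seed = 4)
  expect_identical(f1$threshold, f2$threshold)
  expect_identical(f1$sig, f2$sig)
})

test_that("degenerate designs and masks are refused", {
  tr <- fx_truth()
  imgs <- fp_cohort(tr, n_per_cell = 1, seed = 15)
  expect_error(fit_pixelwise_glm(imgs), ">= 2 images")
  fit <- fit_pixelwise_glm(fp_cohort(tr, seed = 17))
  expect_error(fwe_threshold(fit, "omnibus", matrix(FALSE, 24, 20), 100),
               "mask")
  rec <- data.frame(disruption = "Ipsi", latbin = "Early", direction = "R")
  expect_error(synth_face_pair(rec, fx_truth(),
                               face_image_params(height = 0, width = 0)),
               "mask")
})
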