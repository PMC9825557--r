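#' Parameters of the synthetic face difference images
#'
#' Defines the image geometry and the scleral regions (two ellipses in the
#' upper face, where fearful expressions widen the visible sclera). Images
#' are generated pre-aligned in a common frame.
#'
#' @param height,width image size in pixels.
#' @param noise_sd pixel noise SD before spatial smoothing.
#' @param noise_fwhm FWHM (pixels) of the Gaussian smoothing that makes the
#'   noise field spatially correlated.
#' @return list of class `face_image_params`.
#' @export
face_image_params <- function(height = 48, width = 40, noise_sd = 1,
                              noise_fwhm = 3) {
  structure(list(height = height, width = width, noise_sd = noise_sd,
                 noise_fwhm = noise_fwhm), class = "face_image_params")
}

#' Binary masks over the synthetic face frame
#'
#' `sclera_mask()` marks the two eye-white ellipses (centred at 30% height,
#' 30%/70% width); `upper_face_mask()` marks the upper half of the image,
#' the a-priori search region for eye-related features.
#'
#' @param params a [face_image_params()].
#' @return logical matrix (height x width).
#' @export
sclera_mask <- function(params) {
  h <- params$height; w <- params$width
  r <- row(matrix(0, h, w)); cc <- col(matrix(0, h, w))
  m1 <- ((r - 0.30 * h) / (0.06 * h))^2 + ((cc - 0.30 * w) / (0.11 * w))^2 <= 1
  m2 <- ((r - 0.30 * h) / (0.06 * h))^2 + ((cc - 0.70 * w) / (0.11 * w))^2 <= 1
  m1 | m2
}

#' @rdname sclera_mask
#' @export
upper_face_mask <- function(params) {
  m <- matrix(FALSE, params$height, params$width)
  m[seq_len(floor(params$height / 2)), ] <- TRUE
  m
}

#' Synthesize one attended-minus-neglected face difference image
#'
#' A smooth (spatially correlated Gaussian) noise field plus, on trials
#' whose condition carries a scleral effect, signal in the scleral regions.
#' The ground-truth effect follows `truth$sclera`: the scleral signal is
#' present on Early trials with a per-disruption-condition weight
#' (strongest when disruption is ipsilateral to the fearful face, absent
#' when contralateral), emulating scleral exposure driving fast orienting.
#'
#' @param record one trial-record row (`disruption`, `latbin`, `direction`).
#' @param truth a [ground_truth()] (uses `truth$sclera`).
#' @param image_params a [face_image_params()].
#' @param seed integer seed.
#' @return list of class `diff_image`: `pixels` (matrix), trial `labels`,
#'   and the ground-truth signal amplitude.
#' @export
synth_face_pair <- function(record, truth, image_params = face_image_params(),
                            seed = 1L) {
  mask <- sclera_mask(image_params)
  if (!any(mask)) stop("empty sclera mask")
  h <- image_params$height; w <- image_params$width
  noise <- with_seed(seed, matrix(rnorm(h * w), h, w))
  if (image_params$noise_fwhm > 0) {
    noise <- smooth2d(noise, rep(image_params$noise_fwhm, 2))
    noise <- noise / sd(noise) # unit variance after smoothing
  }
  img <- image_params$noise_sd * noise
  wgt <- truth$sclera$weights[[record$disruption]] %||% 0
  amp <- 0
  if (!is.null(record$latbin) && !is.na(record$latbin) &&
      record$latbin == "Early" && wgt != 0) {
    amp <- truth$sclera$amplitude * wgt
    img[mask] <- img[mask] + amp
  }
  structure(list(pixels = img,
                 labels = data.frame(disruption = record$disruption,
                                     latbin = record$latbin %||% NA_character_,
                                     side = record$direction %||% "R",
                                     stringsAsFactors = FALSE),
                 truth = list(amplitude = amp)),
            class = "diff_image")
}

#' Synthesize the difference images of a cohort's Yield trials
#'
#' Median-splits the analysable Yield trials and generates one difference
#' image per trial.
#'
#' @param records trial table from [simulate_behaviour()].
#' @param truth a [ground_truth()].
#' @param image_params a [face_image_params()].
#' @param seed master seed.
#' @return list with `images` (list of `diff_image`) and `records`.
#' @export
synth_face_cohort <- function(records, truth,
                              image_params = face_image_params(), seed = 1L) {
  keep <- records$instruction == "Yield" & records$qc == "valid"
  rec <- records[keep, , drop = FALSE]
  if (is.null(rec$latbin)) rec <- median_split(rec)
  rec$trial_uid <- rec$trial_uid %||% seq_len(nrow(rec))
  iseed <- substream_seeds(seed, 2^25 + rec$trial_uid)
  images <- lapply(seq_len(nrow(rec)), function(i)
    synth_face_pair(rec[i, ], truth, image_params, seed = iseed[i]))
  list(images = images, records = rec)
}
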