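# Deterministic inference crop/resize and the stochastic training
# crop/augmentation chain.
#
# The inference path (center_crop -> resize_to_input) is fully deterministic;
# the training path randomises the crop position inside a horizontally
# centered band and applies geometric and color jitter.  Augmentation order
# is fixed: geometric -> gamma -> saturation -> temperature -> noise -> blur.

#' Crop geometry specification
#'
#' For the nominal 2256 x 1440 scanner frame the square crop is the full
#' short side (1440) and the training band is the middle 1640 columns, so
#' training x-offsets range over `[308, 508]` (0-based) while inference fixes
#' the center crop at x = 408.
#'
#' @param source_size `c(height, width)` of the source images.
#' @param crop_size side of the square crop, <= `min(source_size)`.
#' @param train_band width (px) of the horizontally centered band from which
#'   training crops are drawn; >= `crop_size`.
#' @return a `crop_spec` object.
#' @export
crop_spec <- function(source_size = c(1440, 2256), crop_size = 1440,
                      train_band = 1640) {
  if (length(source_size) != 2 || any(source_size < 1))
    stopf("source_size must be c(height, width)")
  if (crop_size > min(source_size))
    stopf("crop_size %d exceeds min(source dims) = %d", crop_size, min(source_size))
  if (train_band < crop_size)
    stopf("train_band (%d) must be >= crop_size (%d)", train_band, crop_size)
  if (train_band > max(source_size))
    stopf("train_band (%d) exceeds the source extent", train_band)
  structure(list(source_size = as.integer(source_size),
                 crop_size = as.integer(crop_size),
                 train_band = as.integer(train_band)),
            class = "crop_spec")
}

#' Default crop geometry for a source size
#'
#' Non-square sources use the full short side as the square crop with a band
#' scaled as 1640/1440 of the crop (the scanner-frame convention); square
#' sources use a 7/8 crop so the training crop still has positional jitter.
#'
#' @param source_size `c(height, width)`.
#' @return a [crop_spec()].
#' @export
default_crop_spec <- function(source_size) {
  h <- source_size[1]; w <- source_size[2]
  if (h == w) {
    cs <- max(64L, as.integer(round(h * 7 / 8)))
    band <- min(w, as.integer(round(cs * 1640 / 1440)))
  } else {
    cs <- min(h, w)
    band <- min(max(h, w), as.integer(round(cs * 1640 / 1440)))
  }
  crop_spec(source_size, cs, band)
}

#' Center-crop origin for a source size
#'
#' The 0-based origin of the square center crop:
#' `(floor((W - c)/2), floor((H - c)/2))`; e.g. 408, 0 for a 1440 px crop of
#' a 2256 x 1440 frame.
#'
#' @param source_size `c(height, width)`.
#' @param crop_size square crop side.
#' @return named integer `c(x0, y0)`, 0-based.
#' @export
crop_origin <- function(source_size, crop_size) {
  c(x0 = as.integer((source_size[2] - crop_size) %/% 2),
    y0 = as.integer((source_size[1] - crop_size) %/% 2))
}

#' Training crop offset ranges for a crop geometry
#'
#' The inclusive 0-based ranges of the x and y offsets drawn by
#' [random_crop_train()]: x uniform on
#' `[(W - band)/2, (W - band)/2 + band - c]`, y analogous when the height
#' exceeds the crop.
#'
#' @param spec a [crop_spec()].
#' @return list with integer ranges `x` and `y` (`c(lo, hi)`).
#' @export
train_offset_range <- function(spec) {
  stopifnot(inherits(spec, "crop_spec"))
  rng <- function(extent, band) {
    band <- min(band, extent)
    lo <- (extent - band) %/% 2
    c(as.integer(lo), as.integer(lo + band - spec$crop_size))
  }
  list(x = rng(spec$source_size[2], spec$train_band),
       y = rng(spec$source_size[1], min(spec$train_band, spec$source_size[1])))
}

#' Deterministic center crop
#'
#' Square crop with 0-based origin `(floor((W - c)/2), floor((H - c)/2))`.
#'
#' @param image height x width x 3 array.
#' @param crop_size square side in pixels, or a [crop_spec()].
#' @return the cropped `crop_size` x `crop_size` x 3 array.
#' @export
center_crop <- function(image, crop_size) {
  assert_image(image)
  cs <- if (inherits(crop_size, "crop_spec")) crop_size$crop_size else as.integer(crop_size)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < cs || W < cs)
    stopf("image %dx%d is smaller than the %d px crop", H, W, cs)
  x0 <- (W - cs) %/% 2  # 0-based origins
  y0 <- (H - cs) %/% 2
  image[(y0 + 1):(y0 + cs), (x0 + 1):(x0 + cs), , drop = FALSE]
}

# 0-based uniform crop offset within a centered band: lo = floor((extent -
# band)/2), offset ~ Uniform{lo, ..., lo + band - crop}.
sample_crop_offset <- function(extent, band, crop) {
  band <- min(band, extent)
  lo <- (extent - band) %/% 2
  if (band == crop) return(lo)
  lo + sample.int(band - crop + 1, 1) - 1L
}

#' Random training crop within a centered band
#'
#' Draws the square crop uniformly from the horizontally centered
#' `train_band`-wide section (and analogously in y when the image is taller
#' than the crop).  With `train_band == crop_size` this degenerates to
#' [center_crop()].
#'
#' @param image height x width x 3 array.
#' @param spec a [crop_spec()].
#' @return cropped array with attribute `offset` = c(x0, y0), 0-based.
#' @export
random_crop_train <- function(image, spec) {
  assert_image(image)
  cs <- spec$crop_size
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < cs || W < cs)
    stopf("image %dx%d is smaller than the %d px crop", H, W, cs)
  x0 <- sample_crop_offset(W, spec$train_band, cs)
  y0 <- sample_crop_offset(H, min(spec$train_band, H), cs)
  out <- image[(y0 + 1):(y0 + cs), (x0 + 1):(x0 + cs), , drop = FALSE]
  attr(out, "offset") <- c(x0 = x0, y0 = y0)
  out
}

#' Resize a square image to the network input resolution
#'
#' Bilinear interpolation (EBImage); resizing to the current size is an exact
#' identity.  Constant images stay constant.
#'
#' @param image square height x width x 3 array.
#' @param side target side in pixels (default 512, the full-scale input).
#' @return `side` x `side` x 3 array.
#' @export
resize_to_input <- function(image, side = 512) {
  assert_image(image)
  d <- dim(image)
  if (d[1] != d[2]) stopf("resize_to_input expects a square image, got %dx%d", d[1], d[2])
  if (d[1] == side) return(image)
  out <- EBImage::resize(image, w = side, h = side, filter = "bilinear")
  array(as.numeric(out), c(side, side, 3))
}

#' Augmentation configuration
#'
#' Ranges at their identity values (`c(1, 1)` scales, zero sigmas, no flip,
#' rotation set `{0}`) switch the corresponding jitter off; the inference
#' default [identity_augmentation()] is the all-identity configuration.
#' "Temperature" jitter is an opposite-sign multiplicative scaling of the red
#' and blue channels (R x t, B / t).
#'
#' @param flip random horizontal flip with probability 1/2.
#' @param rotations set of rotation angles (multiples of 90 degrees) sampled
#'   uniformly.
#' @param gamma_range range of the gamma exponent.
#' @param saturation_range range of the saturation scale.
#' @param temperature_range range of the red/blue temperature scale.
#' @param noise_sigma standard deviation of additive Gaussian noise (on the
#'   `[0, 1]` intensity scale).
#' @param blur_sigma_range range of the Gaussian blur sigma (px); draws
#'   below 0.05 skip the blur.
#' @return an `augmentation_config` object.
#' @export
augmentation_config <- function(flip = TRUE, rotations = c(0, 90, 180, 270),
                                gamma_range = c(0.8, 1.25),
                                saturation_range = c(0.8, 1.2),
                                temperature_range = c(0.95, 1.05),
                                noise_sigma = 0.01,
                                blur_sigma_range = c(0, 0.8)) {
  if (any(rotations %% 90 != 0))
    stopf("rotations must be multiples of 90 degrees")
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && all(r > 0)
  if (!rng_ok(gamma_range) || !rng_ok(saturation_range) || !rng_ok(temperature_range))
    stopf("jitter ranges must be positive c(lo, hi) with lo <= hi")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (length(blur_sigma_range) != 2 || any(blur_sigma_range < 0) ||
      blur_sigma_range[1] > blur_sigma_range[2])
    stopf("blur_sigma_range must be non-negative c(lo, hi)")
  structure(list(flip = flip, rotations = rotations, gamma_range = gamma_range,
                 saturation_range = saturation_range,
                 temperature_range = temperature_range,
                 noise_sigma = noise_sigma, blur_sigma_range = blur_sigma_range),
            class = "augmentation_config")
}

#' @rdname augmentation_config
#' @export
identity_augmentation <- function() {
  augmentation_config(flip = FALSE, rotations = 0, gamma_range = c(1, 1),
                      saturation_range = c(1, 1), temperature_range = c(1, 1),
                      noise_sigma = 0, blur_sigma_range = c(0, 0))
}

rot90k <- function(image, k) {
  k <- ((k %% 360) / 90) %% 4
  if (k == 0) return(image)
  for (i in seq_len(k)) {
    d <- dim(image)
    # 90 degrees counter-clockwise: new[h', w'] = old[w', H - h' + 1]
    image <- aperm(image, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  image
}

#' Apply the stochastic training augmentation chain
#'
#' Order: geometric (flip, rotation) -> gamma -> saturation -> temperature ->
#' additive Gaussian noise -> blur.  Intensities are clipped back to
#' `[0, 1]` after each color operation; shape and channel count never change.
#' The identity configuration returns the input unchanged.
#'
#' @param image height x width x 3 array in `[0, 1]`.
#' @param config an [augmentation_config()].
#' @return augmented array, same shape.
#' @export
augment <- function(image, config = augmentation_config()) {
  assert_image(image)
  if (config$flip && runif(1) < 0.5)
    image <- image[, dim(image)[2]:1, , drop = FALSE]
  if (length(config$rotations) > 1 || config$rotations[1] %% 360 != 0) {
    ang <- config$rotations[sample.int(length(config$rotations), 1)]
    image <- rot90k(image, ang)
  }
  if (config$gamma_range[1] != 1 || config$gamma_range[2] != 1) {
    g <- runif(1, config$gamma_range[1], config$gamma_range[2])
    image <- clip01(image)^g
  }
  if (config$saturation_range[1] != 1 || config$saturation_range[2] != 1) {
    s <- runif(1, config$saturation_range[1], config$saturation_range[2])
    gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
    for (ch in 1:3) image[, , ch] <- gray + s * (image[, , ch] - gray)
    image <- clip01(image)
  }
  if (config$temperature_range[1] != 1 || config$temperature_range[2] != 1) {
    tt <- runif(1, config$temperature_range[1], config$temperature_range[2])
    image[, , 1] <- image[, , 1] * tt
    image[, , 3] <- image[, , 3] / tt
    image <- clip01(image)
  }
  if (config$noise_sigma > 0) {
    image <- clip01(image + array(rnorm(length(image), 0, config$noise_sigma),
                                  dim(image)))
  }
  if (config$blur_sigma_range[2] > 0) {
    sg <- runif(1, config$blur_sigma_range[1], config$blur_sigma_range[2])
    if (sg > 0.05) {
      image <- clip01(array(as.numeric(EBImage::gblur(image, sigma = sg)),
                            dim(image)))
    }
  }
  image
}
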