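# In-memory image convention
#
# Images are numeric arrays of dim (height, width, 3) with RGB intensities in
# [0, 1].  Rendered and file-backed images are quantised to 8-bit levels
# (k/255), so checksums and PNG round-trips are byte-stable; intermediate
# preprocessing stages may hold continuous values.

#' Quantise an image to 8-bit intensity levels
#'
#' Rounds intensities to the nearest of the 256 8-bit levels `k/255`.  The
#' renderer applies this as its final step so that identical generator seeds
#' give byte-identical images and PNG round-trips are lossless.
#'
#' @param img numeric array, height x width x 3, values in `[0, 1]`.
#' @return the quantised array, same shape.
#' @export
quantize8 <- function(img) {
  round(clip01(img) * 255) / 255
}

#' Write an image to a PNG file
#'
#' @param img numeric array, height x width x 3, values in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clip01(img), target = path)
  invisible(path)
}

#' Read a PNG image
#'
#' @param path PNG file path.
#' @return numeric array, height x width x 3, values in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

assert_image <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stopf("%s must be a height x width x 3 array", what)
  invisible(img)
}
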