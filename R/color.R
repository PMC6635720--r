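# Colour-space conversions used by the segmentation and feature stages.

#' Yellow channel of the naive CMYK transform
#'
#' Converts an 8-bit RGB image to the Y (yellow) component of the naive
#' CMYK decomposition: with channels scaled to \[0, 1\],
#' `K = 1 - max(R, G, B)` and `Y = (1 - B - K) / (1 - K)`. Stained white
#' blood cells are blue/purple dominated, so they carry essentially no
#' yellow and appear dark in this channel, while the slightly warm smear
#' background and red cells appear bright.
#'
#' @param img H x W x 3 RGB array with values in \[0, 255\].
#' @return Numeric H x W matrix in \[0, 1\]. Pure black pixels (K = 1) map
#'   to 0.
#' @export
rgb_to_cmyk_y <- function(img) {
  assert_rgb_image(img)
  r <- img[, , 1] / 255; g <- img[, , 2] / 255; b <- img[, , 3] / 255
  k <- 1 - pmax(r, g, b)
  denom <- 1 - k
  y <- ifelse(denom <= .Machine$double.eps, 0, (1 - b - k) / denom)
  y[y < 0] <- 0; y[y > 1] <- 1
  y
}

#' Convert an RGB image to CIELAB
#'
#' Standard sRGB (D65) to CIELAB conversion of every pixel.
#'
#' @param img H x W x 3 RGB array with values in \[0, 255\].
#' @return H x W x 3 array with L*, a*, b* slices on the conventional
#'   scales (L* in \[0, 100\], a*/b* roughly \[-128, 127\]).
#' @export
rgb_to_lab <- function(img) {
  assert_rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- matrix(img, ncol = 3) / 255
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  array(lab, dim = c(h, w, 3))
}

# CIELAB of a set of pixels only (avoids converting a full frame when a
# small masked region is needed).
lab_of_pixels <- function(img, mask) {
  assert_rgb_image(img); assert_mask(mask)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  npx <- prod(dim(img)[1:2])
  px <- cbind(img[idx], img[npx + idx], img[2 * npx + idx]) / 255
  grDevices::convertColor(px, from = "sRGB", to = "Lab")
}
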