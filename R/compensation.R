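# Color-space conversion and brightness compensation.
#
# Endoscopic frames are captured with a moving light source, so the average
# brightness varies frame to frame. Before hue features are compared across
# frames, every image is shifted in luma so its mean Y equals a common target
# (125 by default), leaving the chroma planes untouched.

# ITU-R BT.601 full-range coefficients (Y spans [0, 255], Cb/Cr centered at 128).
.ycbcr_fwd <- matrix(c(
   0.299,     0.587,     0.114,
  -0.168736, -0.331264,  0.5,
   0.5,      -0.418688, -0.081312
), nrow = 3, byrow = TRUE)

#' Convert an RGB image to YCbCr (BT.601 full range)
#'
#' Planes are returned unrounded so that round trips and downstream feature
#' math keep full precision; achromatic pixels map to Cb = Cr = 128.
#'
#' @param image numeric array dim (rows, cols, 3) with values in \[0, 255\].
#' @return object of class `lq_ycbcr`: list with matrices `Y`, `Cb`, `Cr`.
#' @export
#' @examples
#' g <- array(128, dim = c(2, 2, 3))
#' y <- rgb_to_ycbcr(g)
#' stopifnot(all(abs(y$Cb - 128) < 1e-9))
rgb_to_ycbcr <- function(image) {
  check_rgb(image)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  structure(list(
    Y  = .ycbcr_fwd[1, 1] * r + .ycbcr_fwd[1, 2] * g + .ycbcr_fwd[1, 3] * b,
    Cb = 128 + .ycbcr_fwd[2, 1] * r + .ycbcr_fwd[2, 2] * g + .ycbcr_fwd[2, 3] * b,
    Cr = 128 + .ycbcr_fwd[3, 1] * r + .ycbcr_fwd[3, 2] * g + .ycbcr_fwd[3, 3] * b
  ), class = "lq_ycbcr")
}

#' Convert a YCbCr image back to RGB
#'
#' Inverse of [rgb_to_ycbcr()]; channels are clipped to \[0, 255\] but not
#' rounded. For 8-bit inputs the round trip is exact to within one gray level.
#'
#' @param ycbcr an `lq_ycbcr` object.
#' @return numeric RGB array.
#' @export
ycbcr_to_rgb <- function(ycbcr) {
  if (!inherits(ycbcr, "lq_ycbcr")) lq_stop("expected an lq_ycbcr object")
  y <- ycbcr$Y; cb <- ycbcr$Cb - 128; cr <- ycbcr$Cr - 128
  out <- array(0, dim = c(nrow(y), ncol(y), 3))
  out[, , 1] <- y + 1.402 * cr
  out[, , 2] <- y - 0.344136 * cb - 0.714136 * cr
  out[, , 3] <- y + 1.772 * cb
  clamp(out, 0, 255)
}

#' Luma plane of an RGB image
#'
#' The gray image used by all sharpness and segmentation stages is the Y
#' plane of the BT.601 transform.
#'
#' @param image RGB array.
#' @return numeric matrix in \[0, 255\].
#' @export
rgb_to_gray <- function(image) rgb_to_ycbcr(image)$Y

#' Brightness compensation by luma histogram shifting
#'
#' Implements I(x,y) = O(x,y) + (S - Om) on the Y plane: the image is
#' converted to YCbCr, every Y value is shifted by the difference between
#' the target S and the pre-shift mean Om, clipped to \[0, 255\], and
#' converted back to RGB. Chroma planes are preserved exactly, so hue
#' features are invariant to the compensation. When no pixel clips, the
#' post-shift mean luma equals `target` up to rounding.
#'
#' @param image RGB array in \[0, 255\].
#' @param target desired mean luma (default 125).
#' @return RGB array with attributes `shift` (the applied S - Om) and
#'   `clip_fraction` (share of pixels clipped in Y). A warning reports any
#'   clipping.
#' @export
histogram_shift <- function(image, target = 125) {
  check_rgb(image)
  ycc <- rgb_to_ycbcr(image)
  om <- mean(ycc$Y)
  shift <- target - om
  y2 <- ycc$Y + shift
  clip_fraction <- mean(y2 < 0 | y2 > 255)
  if (clip_fraction > 0)
    warning(sprintf("histogram_shift: %.2f%% of pixels clipped in Y",
                    100 * clip_fraction))
  ycc$Y <- clamp(y2, 0, 255)
  out <- ycbcr_to_rgb(ycc)
  attr(out, "shift") <- shift
  attr(out, "clip_fraction") <- clip_fraction
  out
}
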