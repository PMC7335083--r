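# Frame screening and sharp-frame selection.
#
# A laryngoscopy recording yields a stack of frames, most of which are
# useless: the scope is outside the throat (low red content) or the frame is
# motion/defocus blurred. Screening removes non-throat frames with a red
# fraction threshold, removes blurred frames whose gray-level variance falls
# below the stack average, and selection then picks the single sharpest
# survivor by one of four focus scores. All scores operate on the luma plane.

#' Mean red chromatic fraction of an RGB image
#'
#' Per pixel R / (R + G + B), with 0/0 treated as 0, averaged over the image.
#' Frames outside the throat are dominated by gray/blue content and fall
#' below the 0.4 screening threshold, while mucosa is strongly red.
#'
#' @param image RGB array in \[0, 255\].
#' @return scalar in \[0, 1\].
#' @export
red_fraction <- function(image) {
  check_rgb(image)
  s <- image[, , 1] + image[, , 2] + image[, , 3]
  frac <- ifelse(s == 0, 0, image[, , 1] / s)
  mean(frac)
}

#' Gray-level variance focus score
#'
#' Population variance of the gray levels. Blur flattens contours and
#' strictly lowers the score on textured images.
#'
#' @param gray numeric gray matrix.
#' @return non-negative scalar.
#' @export
variance_score <- function(gray) {
  check_gray(gray)
  mean((gray - mean(gray))^2)
}

#' Sum-modulus-difference (SMD) focus score
#'
#' Sum of absolute gray differences over all horizontally adjacent pixel
#' pairs (SMD_x) plus all vertically adjacent pairs (SMD_y). This is the
#' default selection score: a cheap first-derivative high-pass response.
#'
#' @param gray gray matrix, at least 2x2.
#' @return non-negative scalar.
#' @export
smd_score <- function(gray) {
  check_gray(gray, c(2L, 2L))
  smd_x <- sum(abs(gray[, -1, drop = FALSE] - gray[, -ncol(gray), drop = FALSE]))
  smd_y <- sum(abs(gray[-1, , drop = FALSE] - gray[-nrow(gray), , drop = FALSE]))
  smd_x + smd_y
}

#' Sobel gradient-magnitude focus score
#'
#' Sum over interior pixels of sqrt(Gx^2 + Gy^2) with the standard 3x3
#' Sobel masks; border pixels are excluded (no padding).
#'
#' @param gray gray matrix, at least 3x3.
#' @return non-negative scalar.
#' @export
sobel_score <- function(gray) {
  check_gray(gray, c(3L, 3L))
  nr <- nrow(gray); nc <- ncol(gray)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  gx <- (gray[i - 1, j + 1] + 2 * gray[i, j + 1] + gray[i + 1, j + 1]) -
        (gray[i - 1, j - 1] + 2 * gray[i, j - 1] + gray[i + 1, j - 1])
  gy <- (gray[i + 1, j - 1] + 2 * gray[i + 1, j] + gray[i + 1, j + 1]) -
        (gray[i - 1, j - 1] + 2 * gray[i - 1, j] + gray[i - 1, j + 1])
  sum(sqrt(gx^2 + gy^2))
}

#' Laplacian energy focus score
#'
#' Sum of squared responses of the discretized Laplacian kernel
#' \[0 1 0; 1 -4 1; 0 1 0\] over interior pixels (no padding).
#'
#' @param gray gray matrix, at least 3x3.
#' @return non-negative scalar.
#' @export
laplacian_score <- function(gray) {
  check_gray(gray, c(3L, 3L))
  nr <- nrow(gray); nc <- ncol(gray)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  lap <- gray[i - 1, j] + gray[i + 1, j] + gray[i, j - 1] + gray[i, j + 1] -
    4 * gray[i, j]
  sum(lap^2)
}

#' Per-frame sharpness and screening report
#'
#' Computes all four focus scores plus the red fraction for every frame of a
#' stack. Used by [screen()] and [select_sharpest()] and handy for
#' diagnosing why a frame was dropped.
#'
#' @param stack list of RGB arrays.
#' @return data.frame with columns frame, red_fraction, variance, smd,
#'   sobel, laplacian.
#' @export
sharpness_report <- function(stack) {
  if (!is.list(stack) || !length(stack)) lq_stop("expected a non-empty list of frames")
  rows <- lapply(seq_along(stack), function(i) {
    img <- check_rgb(stack[[i]])
    g <- rgb_to_gray(img)
    data.frame(
      frame = i,
      red_fraction = red_fraction(img),
      variance = variance_score(g),
      smd = smd_score(g),
      sobel = sobel_score(g),
      laplacian = laplacian_score(g)
    )
  })
  do.call(rbind, rows)
}

#' Screen a frame stack for usable throat frames
#'
#' Two single-pass filters, in order: (1) frames with red fraction below
#' `red_threshold` are removed (non-throat); (2) the mean variance of the
#' remaining frames is computed once and frames strictly below that mean are
#' removed (blurred). Frame order is preserved.
#'
#' @param stack list of RGB arrays.
#' @param red_threshold red-fraction cutoff (default 0.4).
#' @return integer vector of surviving 1-based frame indices; empty (with a
#'   warning) when everything is filtered out.
#' @export
screen <- function(stack, red_threshold = 0.4) {
  rep_df <- sharpness_report(stack)
  keep <- which(rep_df$red_fraction >= red_threshold)
  if (!length(keep)) {
    warning("screen: all frames removed by the red-fraction filter")
    return(integer(0))
  }
  v <- rep_df$variance[keep]
  keep <- keep[v >= mean(v)]
  if (!length(keep)) warning("screen: all frames removed by the variance filter")
  keep
}

#' Select the sharpest frame among candidates
#'
#' @param stack list of RGB arrays.
#' @param indices candidate frame indices (e.g. the output of [screen()]).
#' @param method one of "smd" (default), "variance", "sobel", "laplacian".
#' @return the index with maximal score; ties broken by lowest index.
#' @export
select_sharpest <- function(stack, indices = seq_along(stack),
                            method = c("smd", "variance", "sobel", "laplacian")) {
  method <- match.arg(method)
  if (!length(indices)) lq_stop("select_sharpest: empty candidate set")
  scores <- vapply(indices, function(i) {
    g <- rgb_to_gray(check_rgb(stack[[i]]))
    switch(method,
           smd = smd_score(g),
           variance = variance_score(g),
           sobel = sobel_score(g),
           laplacian = laplacian_score(g))
  }, numeric(1))
  indices[which.max(scores)]
}
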