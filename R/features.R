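# Hue and GLCM texture features, and Fisher linear discriminant ranking.
#
# 36 features per segmented image: six chromatic channels (R, G, B, HSV hue,
# Cb, Cr) averaged over the arytenoid cartilage and over each vocal cord
# (reported as max/min across the two cords), the vocal-cord-to-arytenoid
# ratio per channel, and four GLCM texture statistics (contrast, energy,
# correlation, homogeneity) per region. Features are ranked by the
# two-class Fisher criterion f = (mu1 - mu2)^2 / (s1^2 + s2^2).

#' Mean of a chromatic channel over a masked region
#'
#' R, G, B are plain means; Cb, Cr come from the BT.601 transform
#' (achromatic pixels give 128); H is the HSV hue in degrees, averaged
#' circularly (vector mean of angles) to avoid the 0/360 wrap artifact.
#'
#' @param image RGB array in \[0, 255\].
#' @param mask logical matrix, non-empty.
#' @param channel one of "R", "G", "B", "H", "Cb", "Cr".
#' @return scalar; H in \[0, 360).
#' @export
mean_channel <- function(image, mask, channel = c("R", "G", "B", "H", "Cb", "Cr")) {
  channel <- match.arg(channel)
  check_rgb(image)
  if (!is_mask(mask) || !any(mask)) lq_stop("mean_channel: empty mask")
  if (channel %in% c("R", "G", "B")) {
    ch <- match(channel, c("R", "G", "B"))
    return(mean(image[, , ch][mask]))
  }
  if (channel %in% c("Cb", "Cr")) {
    ycc <- rgb_to_ycbcr(image)
    return(mean(ycc[[channel]][mask]))
  }
  rgb <- rbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  h <- grDevices::rgb2hsv(rgb, maxColorValue = 255)[1, ] * 2 * pi
  ang <- atan2(mean(sin(h)), mean(cos(h))) * 180 / pi
  (ang + 360) %% 360
}

#' Gray-level co-occurrence matrix of a masked region
#'
#' Gray levels are linearly quantized to `levels` bins over \[0, 255\];
#' horizontally displaced pixel pairs (angle 0, the direction used for the
#' reflux analysis) with both members inside the mask are counted in both
#' orders (symmetric GLCM) and the matrix is normalized to sum 1.
#'
#' @param gray gray matrix in \[0, 255\].
#' @param mask logical matrix (same dimensions).
#' @param distance pair displacement in pixels.
#' @param angle only 0 (degrees) is supported.
#' @param levels quantization level count k (default 8).
#' @return object of class `lq_glcm`: k x k probability matrix with
#'   attributes `levels`, `distance`, `angle`.
#' @export
glcm_matrix <- function(gray, mask, distance = 1L, angle = 0, levels = 8L) {
  check_gray(gray)
  if (!is_mask(mask) || !all(dim(mask) == dim(gray)))
    lq_stop("mask must be a logical matrix matching the image")
  if (angle != 0) lq_stop("only angle = 0 is supported")
  if (distance < 1 || distance >= ncol(gray))
    lq_stop("distance must be in [1, ncols)")
  q <- pmin(floor(clamp(gray, 0, 255) / 256 * levels), levels - 1L)
  nc <- ncol(gray)
  lhs <- seq_len(nc - distance)
  rhs <- lhs + distance
  valid <- mask[, lhs, drop = FALSE] & mask[, rhs, drop = FALSE]
  if (!any(valid)) lq_stop("no valid horizontal pixel pair inside the mask")
  il <- q[, lhs, drop = FALSE][valid]
  ir <- q[, rhs, drop = FALSE][valid]
  counts <- tabulate(il * levels + ir + 1L, nbins = levels^2) +
    tabulate(ir * levels + il + 1L, nbins = levels^2)
  p <- matrix(counts / sum(counts), levels, levels, byrow = TRUE)
  structure(p, class = c("lq_glcm", class(p)),
            levels = levels, distance = distance, angle = angle)
}

check_glcm <- function(p) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) lq_stop("expected a square GLCM matrix")
  if (abs(sum(p) - 1) > 1e-6) lq_stop("GLCM is not normalized (sum != 1)")
  invisible(p)
}

#' GLCM energy (equalization)
#'
#' Sum of squared entries; in \[0, 1\], reaching 1 iff the region's gray
#' levels are identical (a single nonzero entry).
#' @param p normalized GLCM matrix.
#' @return scalar.
#' @export
glcm_energy <- function(p) {
  check_glcm(p)
  sum(p^2)
}

#' GLCM contrast
#'
#' sum (i - j)^2 p_ij; 0 for a constant region, at most (k - 1)^2.
#' @param p normalized GLCM matrix.
#' @return scalar.
#' @export
glcm_contrast <- function(p) {
  check_glcm(p)
  k <- nrow(p)
  d <- outer(seq_len(k), seq_len(k), "-")
  sum(d^2 * p)
}

#' GLCM correlation
#'
#' sum (i - mu_i)(j - mu_j) p_ij / (s_i s_j) with marginal means and sds;
#' defined as 0 when either marginal sd is 0.
#' @param p normalized GLCM matrix.
#' @return scalar in \[-1, 1\].
#' @export
glcm_correlation <- function(p) {
  check_glcm(p)
  k <- nrow(p)
  i <- seq_len(k)
  pi_ <- rowSums(p); pj <- colSums(p)
  mi <- sum(i * pi_); mj <- sum(i * pj)
  si <- sqrt(sum((i - mi)^2 * pi_)); sj <- sqrt(sum((i - mj)^2 * pj))
  if (si == 0 || sj == 0) return(0)
  sum(outer(i - mi, i - mj) * p) / (si * sj)
}

#' GLCM homogeneity (inverse difference)
#'
#' sum p_ij / (1 + |i - j|); 1 for a constant region.
#' @param p normalized GLCM matrix.
#' @return scalar in (0, 1\].
#' @export
glcm_homogeneity <- function(p) {
  check_glcm(p)
  k <- nrow(p)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  sum(p / (1 + d))
}

region_texture <- function(gray, mask, ...) {
  p <- glcm_matrix(gray, mask, ...)
  c(con = glcm_contrast(p), eng = glcm_energy(p),
    cor = glcm_correlation(p), hom = glcm_homogeneity(p))
}

#' Extract the 36-feature vector from a segmented image
#'
#' Arytenoid hue and texture come from the arytenoid mask; per-cord hue and
#' texture are computed for each vocal cord and reduced elementwise to max
#' and min across the two cords; ratio features divide the mean of the two
#' cord channel means by the arytenoid channel mean.
#'
#' @param image (compensated) RGB array.
#' @param regions list/`lq_regionset` with non-empty masks `glottis`,
#'   `left_vc`, `right_vc`, `arytenoid`.
#' @param ... passed to [glcm_matrix()] (distance, levels).
#' @return named numeric vector of length 36 (names as
#'   [lq_feature_names()]).
#' @export
extract_features <- function(image, regions, ...) {
  check_rgb(image)
  for (nm in c("left_vc", "right_vc", "arytenoid")) {
    m <- regions[[nm]]
    if (is.null(m) || !is_mask(m) || !any(m))
      lq_stop(paste("empty or missing region:", nm), "lq_invalid_input")
  }
  gray <- rgb_to_gray(image)
  chans <- c("R", "G", "B", "H", "Cb", "Cr")
  a_hue <- vapply(chans, function(ch) mean_channel(image, regions$arytenoid, ch),
                  numeric(1))
  l_hue <- vapply(chans, function(ch) mean_channel(image, regions$left_vc, ch),
                  numeric(1))
  r_hue <- vapply(chans, function(ch) mean_channel(image, regions$right_vc, ch),
                  numeric(1))
  a_tex <- region_texture(gray, regions$arytenoid, ...)
  l_tex <- region_texture(gray, regions$left_vc, ...)
  r_tex <- region_texture(gray, regions$right_vc, ...)
  out <- c(
    stats::setNames(a_hue, paste0("A_", chans)),
    stats::setNames(as.vector(rbind(pmax(l_hue, r_hue), pmin(l_hue, r_hue))),
                    as.vector(t(outer(paste0("VC_", chans), c("max", "min"), paste)))),
    stats::setNames((l_hue + r_hue) / 2 / a_hue, paste0("VC/A_", chans)),
    stats::setNames(a_tex, paste0("A_", names(a_tex))),
    stats::setNames(as.vector(rbind(pmax(l_tex, r_tex), pmin(l_tex, r_tex))),
                    as.vector(t(outer(paste0("VC_", names(l_tex)), c("max", "min"), paste))))
  )
  out[lq_feature_names()]
}

#' Two-class Fisher discriminant score of a feature
#'
#' f = (mu1 - mu2)^2 / (s1^2 + s2^2) with per-class sample means and
#' variances. f = 0 when both variances vanish with equal means; Inf when
#' they vanish with different means.
#'
#' @param values numeric vector.
#' @param labels two-level factor/vector, >= 2 samples per class.
#' @return non-negative scalar (possibly Inf).
#' @export
fisher_score <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2)
    lq_stop("fisher_score needs exactly two classes present")
  sp <- split(values, droplevels(labels))
  if (any(lengths(sp) < 2)) lq_stop("each class needs >= 2 samples")
  m <- vapply(sp, mean, numeric(1))
  v <- vapply(sp, stats::var, numeric(1))
  num <- (m[1] - m[2])^2
  den <- v[1] + v[2]
  if (den == 0) return(if (num == 0) 0 else Inf)
  unname(num / den)
}

#' Rank features by Fisher score
#'
#' @param table data.frame/matrix with the 36 feature columns.
#' @param labels two-class labels.
#' @param top_k number of features to select (default 5).
#' @param use_paper_selection if TRUE, `selected` is fixed to the five
#'   canonical features ([lq_selected_features()]) regardless of rank.
#' @return list with `scores` (data.frame feature/f, descending) and
#'   `selected` (character vector).
#' @export
rank_features <- function(table, labels, top_k = 5L, use_paper_selection = FALSE) {
  table <- as.data.frame(table, check.names = FALSE)
  if (!all(lq_feature_names() %in% colnames(table)))
    lq_stop("table must contain all 36 canonical feature columns")
  table <- table[, lq_feature_names(), drop = FALSE]
  f <- vapply(table, fisher_score, numeric(1), labels = labels)
  ord <- order(-f)
  scores <- data.frame(feature = colnames(table)[ord], f = unname(f[ord]),
                       stringsAsFactors = FALSE)
  selected <- if (use_paper_selection) lq_selected_features()
              else scores$feature[seq_len(min(top_k, nrow(scores)))]
  list(scores = scores, selected = selected)
}
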